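# Unit conventions used throughout the package: lengths in Angstrom unless
# a slot says otherwise (pixel pitch in um, detector distance in mm, focus in
# nm), energies in keV, times in fs, scattering vectors in Angstrom^-1 with
# q = 2 sin(theta)/lambda (no 2*pi) so that 1/q is the full-period resolution.

#' Physical constants
#'
#' \code{hc} in keV * Angstrom; \code{keV_J} converts keV to Joule.
#' @keywords internal
.const <- list(hc = 12.3984, keV_J = 1.602176634e-16)

#' Construct a detector geometry
#'
#' @param nFast,nSlow pixel counts (default 81 x 81).
#' @param pixelSize pixel pitch in micrometres (default 1200).
#' @param distance sample-to-detector distance in millimetres (default 130).
#' @param photonEnergy photon energy in keV (default 4.96).
#' @param center beam-axis pixel coordinates (0-based); defaults to the
#'   exact central pixel for odd pixel counts.
#' @return a \linkS4class{DetectorGeometry}.
#' @examples
#' geom <- detectorGeometry()
#' resolutionAtEdge(geom)  # ~7 Angstrom full-period
#' @export
detectorGeometry <- function(nFast = 81L, nSlow = 81L, pixelSize = 1200,
                             distance = 130, photonEnergy = 4.96,
                             center = NULL) {
  nFast <- as.integer(nFast); nSlow <- as.integer(nSlow)
  if (is.null(center)) center <- c((nFast - 1) / 2, (nSlow - 1) / 2)
  new("DetectorGeometry", nFast = nFast, nSlow = nSlow,
      pixelSize = as.numeric(pixelSize), distance = as.numeric(distance),
      photonEnergy = as.numeric(photonEnergy), center = as.numeric(center))
}

#' X-ray wavelength of a geometry or energy
#'
#' @param x a \linkS4class{DetectorGeometry} or a photon energy in keV.
#' @return wavelength in Angstrom.
#' @export
wavelength <- function(x) {
  e <- if (is(x, "DetectorGeometry")) x@photonEnergy else as.numeric(x)
  stopifnot(e > 0)
  .const$hc / e
}

#' Build the pixel-to-q map on the Ewald sphere
#'
#' Maps every detector pixel to its scattering vector
#' \eqn{q = k_{out} - k_{in}} with \eqn{|k| = 1/\lambda}, so that
#' \eqn{|q| = 2\sin\theta/\lambda} where \eqn{2\theta} is the diffraction
#' angle.  Pixel centres sit at integer coordinates; the integration
#' weight is flat (1) for every pixel.
#'
#' @param geom a \linkS4class{DetectorGeometry}.
#' @return a \linkS4class{PixelMap}; pixels are ordered fast-axis first
#'   (column-major over the detector array).
#' @export
buildPixelMap <- function(geom) {
  stopifnot(is(geom, "DetectorGeometry"))
  validObject(geom)
  lam <- wavelength(geom)
  pitch_mm <- geom@pixelSize / 1000  # um -> mm
  i <- rep(seq_len(geom@nFast) - 1L, times = geom@nSlow)
  j <- rep(seq_len(geom@nSlow) - 1L, each = geom@nFast)
  x <- (i - geom@center[1]) * pitch_mm
  y <- (j - geom@center[2]) * pitch_mm
  r <- sqrt(x^2 + y^2)
  two_theta <- atan2(r, geom@distance)
  phi <- atan2(y, x)
  k <- 1 / lam
  qx <- k * sin(two_theta) * cos(phi)
  qy <- k * sin(two_theta) * sin(phi)
  qz <- k * (cos(two_theta) - 1)
  q <- cbind(qx, qy, qz, deparse.level = 0)
  q[r == 0, ] <- 0
  new("PixelMap", q = q, qmag = sqrt(rowSums(q^2)),
      weight = rep(1, length(x)), nFast = geom@nFast, nSlow = geom@nSlow,
      wavelength = lam)
}

#' Full-period resolution at the detector edge
#'
#' Returns \eqn{1/|q_{edge}|} where \eqn{|q_{edge}|} is evaluated at the
#' midpoint of a detector edge (the pixel one half-array width from the
#' beam centre along the fast axis).
#'
#' @param geom a \linkS4class{DetectorGeometry}.
#' @return resolution in Angstrom (full-period convention).
#' @export
resolutionAtEdge <- function(geom) {
  qe <- edgeQ(geom)
  if (qe <= 0) stop("zero-area detector")
  1 / qe
}

#' |q| at the midpoint of the detector edge
#'
#' @param geom a \linkS4class{DetectorGeometry}.
#' @return |q| in Angstrom^-1.
#' @export
edgeQ <- function(geom) {
  stopifnot(is(geom, "DetectorGeometry"))
  validObject(geom)
  half_px <- min(geom@center[1], geom@nFast - 1 - geom@center[1])
  if (half_px <= 0) stop("zero-area detector")
  r_mm <- half_px * geom@pixelSize / 1000
  two_theta <- atan2(r_mm, geom@distance)
  2 * sin(two_theta / 2) / wavelength(geom)
}

#' |q| at the detector corner
#' @param geom a \linkS4class{DetectorGeometry}.
#' @return |q| in Angstrom^-1.
#' @export
cornerQ <- function(geom) {
  pm <- buildPixelMap(geom)
  max(pm@qmag)
}

#' Construct beam parameters
#'
#' @param photonsPerPulse photons per pulse after the optics.
#' @param photonEnergy keV.
#' @param focusFWHM focal full width at half maximum, (x, y) in nm.
#' @param pulseFDHM full duration at half maximum in fs.
#' @return a \linkS4class{BeamParameters}.
#' @export
beamParameters <- function(photonsPerPulse = 7.5e12, photonEnergy = 4.96,
                           focusFWHM = c(250, 160), pulseFDHM = 9) {
  new("BeamParameters", photonsPerPulse = photonsPerPulse,
      photonEnergy = photonEnergy, focusFWHM = focusFWHM,
      pulseFDHM = pulseFDHM)
}

#' Pulse fluence on the rectangular-FWHM focus
#'
#' Pulse energy (photons x photon energy) divided by the rectangular FWHM
#' focal area, in J/cm^2.
#'
#' @param beam a \linkS4class{BeamParameters}.
#' @return fluence in J/cm^2.
#' @examples
#' fluence(beamParameters())  # ~1.5e7 J/cm^2
#' @export
fluence <- function(beam) {
  stopifnot(is(beam, "BeamParameters"))
  validObject(beam)
  area_cm2 <- prod(beam@focusFWHM * 1e-7)  # nm -> cm
  if (area_cm2 <= 0) stop("zero focus area")
  energy_J <- beam@photonsPerPulse * beam@photonEnergy * .const$keV_J
  energy_J / area_cm2
}

#' @describeIn detectorGeometry display method
#' @param object a \linkS4class{DetectorGeometry}
#' @export
setMethod("show", "DetectorGeometry", function(object) {
  cat(sprintf("DetectorGeometry: %d x %d px, %.0f um pitch, %.1f mm, %.3g keV\n",
              object@nFast, object@nSlow, object@pixelSize, object@distance,
              object@photonEnergy))
  cat(sprintf("  lambda = %.4f A, edge |q| = %.4f A^-1 (%.2f A full period)\n",
              wavelength(object), edgeQ(object), resolutionAtEdge(object)))
})

setMethod("show", "PixelMap", function(object) {
  cat(sprintf("PixelMap: %d x %d pixels, |q| in [0, %.4f] A^-1\n",
              object@nFast, object@nSlow, max(object@qmag)))
})
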