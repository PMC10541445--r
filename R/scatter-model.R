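# Atomic scattering model: Cromer-Mann form factors (4 Gaussians + constant,
# crystallographic s = q/2 convention), toy particles, PDB input, hydration
# shells and the parametric damage stand-in.

# International Tables 4-Gaussian coefficients; water ("HOH") is a single
# effective scatterer f_O + 2 f_H (explicit H2O geometry is not modelled).
.cromerMann <- list(
  H = list(ab = cbind(c(0.489918, 0.262003, 0.196767, 0.049879),
                      c(20.6593, 7.74039, 49.5519, 2.20159)), c = 0.001305),
  C = list(ab = cbind(c(2.31000, 1.02000, 1.58860, 0.865000),
                      c(20.8439, 10.2075, 0.568700, 51.6512)), c = 0.215600),
  N = list(ab = cbind(c(12.2126, 3.13220, 2.01250, 1.16630),
                      c(0.005700, 9.89330, 28.9975, 0.582600)), c = -11.529),
  O = list(ab = cbind(c(3.04850, 2.28680, 1.54630, 0.867000),
                      c(13.2771, 5.70110, 0.323900, 32.9089)), c = 0.250800),
  P = list(ab = cbind(c(6.43450, 4.17910, 1.78000, 1.49080),
                      c(1.90670, 27.1570, 0.526000, 68.1645)), c = 1.11490),
  S = list(ab = cbind(c(6.90530, 5.20340, 1.43790, 1.58630),
                      c(1.46790, 22.2151, 0.253600, 56.1720)), c = 0.866900),
  Fe = list(ab = cbind(c(11.7695, 7.35730, 3.52220, 2.30450),
                       c(4.76110, 0.307200, 15.3535, 76.8805)), c = 1.03690))
.cromerMann$HOH <- list(
  ab = rbind(.cromerMann$O$ab,
             cbind(2 * .cromerMann$H$ab[, 1], .cromerMann$H$ab[, 2])),
  c = .cromerMann$O$c + 2 * .cromerMann$H$c)

.elementZ <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, Fe = 26, HOH = 10)

#' Species supported by the scattering model
#' @return character vector of species symbols (including the effective
#'   water scatterer \code{"HOH"}).
#' @export
supportedElements <- function() names(.cromerMann)

#' Atomic scattering factor
#'
#' Cromer-Mann evaluation \eqn{f(q) = \sum_i a_i \exp(-b_i (q/2)^2) + c}
#' (crystallographic \eqn{s = q/2} convention).  At \eqn{q = 0} this
#' equals the species' electron count to within 0.1.
#'
#' @param element species symbol (see \code{\link{supportedElements}}).
#' @param qmag scattering-vector magnitude(s), Angstrom^-1.
#' @return scattering factor in electrons.
#' @examples
#' formFactor("C", 0)  # ~6
#' @export
formFactor <- function(element, qmag) {
  if (!element %in% names(.cromerMann)) stop("unknown element: ", element)
  stopifnot(all(qmag >= 0))
  p <- .cromerMann[[element]]
  s2 <- (qmag / 2)^2
  out <- rep(p$c, length(qmag))
  for (i in seq_len(nrow(p$ab)))
    out <- out + p$ab[i, 1] * exp(-p$ab[i, 2] * s2)
  out
}

# form-factor parameter list and 0-based species index for the C++ kernels
.ffPack <- function(elements) {
  spec <- unique(elements)
  list(ff = lapply(spec, function(e) .cromerMann[[e]]),
       idx = match(elements, spec) - 1L)
}

#' Construct an atomic structure
#'
#' @param elements species symbols.
#' @param positions n x 3 matrix, Angstrom.
#' @param occupancy per-atom effective-electron scale (default 1).
#' @param center if TRUE (default), translate the centroid to the origin.
#' @return an \linkS4class{AtomicStructure}.
#' @export
atomicStructure <- function(elements, positions, occupancy = NULL,
                            center = TRUE) {
  positions <- as.matrix(positions)
  if (is.null(occupancy)) occupancy <- rep(1, length(elements))
  if (center && nrow(positions))
    positions <- sweep(positions, 2, colMeans(positions))
  new("AtomicStructure", elements = as.character(elements),
      positions = unname(positions), occupancy = as.numeric(occupancy))
}

#' Number of atoms
#' @param x an \linkS4class{AtomicStructure}.
#' @return atom count.
#' @export
nAtoms <- function(x) length(x@elements)

setMethod("show", "AtomicStructure", function(object) {
  tb <- table(object@elements)
  cat(sprintf("AtomicStructure: %d scatterers (%s)\n", nAtoms(object),
              paste(sprintf("%s:%d", names(tb), tb), collapse = ", ")))
})

#' Reproducible random toy particle
#'
#' A random cluster of C/N/O atoms inside a ball of diameter
#' \code{extent}, centred on its centroid.  With \code{symmetrize = TRUE}
#' every atom is duplicated under a two-fold rotation about the model
#' z axis, producing an exactly C2-symmetric particle.
#'
#' @param n number of atoms (before symmetrization).
#' @param extent maximum pairwise distance bound, Angstrom.
#' @param seed integer seed.
#' @param symmetrize duplicate atoms under 180 degrees about z.
#' @return an \linkS4class{AtomicStructure}.
#' @export
makeToyParticle <- function(n = 40, extent = 100, seed = 1,
                            symmetrize = FALSE) {
  stopifnot(n >= 1)
  # local RNG without disturbing the caller's stream
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  r <- extent / 2
  # uniform in the ball of radius extent/2
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  rad <- r * stats::runif(n)^(1 / 3)
  pos <- u * rad
  el <- sample(c("C", "N", "O"), n, replace = TRUE,
               prob = c(0.55, 0.2, 0.25))
  .restore_seed(old)
  if (symmetrize) {
    R <- quatToMatrix(axisAngle(c(0, 0, 1), pi))
    pos <- rbind(pos, pos %*% t(R))
    el <- c(el, el)
  }
  atomicStructure(el, pos)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# chemically sensible substitutions for species outside the supported set;
# anything not listed falls back to the nearest-Z supported element
.elementSubstitute <- c(Se = "S", Mo = "Fe", Mn = "Fe", Co = "Fe", Ni = "Fe",
                        Cu = "Fe", Zn = "Fe", Mg = "O", Na = "O", K = "S",
                        Ca = "S", Cl = "S", F = "O", B = "C", I = "Fe")

#' Read an atomic structure from a PDB file
#'
#' Parses ATOM/HETATM records (via the bio3d reader), centres the
#' coordinates on the centroid, and maps species outside the supported
#' set either to a chemically similar supported element (default) or
#' skips them, with a warning either way.
#'
#' @param path PDB file path.
#' @param unsupported \code{"substitute"} (default) or \code{"skip"}.
#' @param keepWater keep crystallographic waters as effective scatterers
#'   (default FALSE).
#' @return an \linkS4class{AtomicStructure}.
#' @export
readPDBStructure <- function(path, unsupported = c("substitute", "skip"),
                             keepWater = FALSE) {
  unsupported <- match.arg(unsupported)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (!keepWater) at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), ]
  if (nrow(at) == 0L) stop("no atoms in PDB file")
  el <- at$elesy
  el[is.na(el) | el == ""] <- substr(trimws(at$elety[is.na(el) | el == ""]), 1, 1)
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
  known <- el %in% supportedElements()
  if (any(!known)) {
    bad <- unique(el[!known])
    if (unsupported == "skip") {
      warning("skipping unsupported element(s): ", paste(bad, collapse = ", "))
      at <- at[known, ]; el <- el[known]
    } else {
      rep_el <- vapply(bad, function(e) {
        if (e %in% names(.elementSubstitute)) .elementSubstitute[[e]]
        else {
          # nearest-Z supported atomic element
          z <- .guessZ(e)
          cand <- .elementZ[setdiff(names(.elementZ), "HOH")]
          names(cand)[which.min(abs(cand - z))]
        }
      }, character(1))
      warning("substituting unsupported element(s): ",
              paste(sprintf("%s->%s", bad, rep_el), collapse = ", "))
      el[!known] <- rep_el[match(el[!known], bad)]
    }
  }
  if (nrow(at) == 0L) stop("no atoms left after element filtering")
  occ <- at$o
  occ[is.na(occ)] <- 1
  atomicStructure(el, cbind(at$x, at$y, at$z), occupancy = occ)
}

# rough atomic number lookup for fallback substitution
.guessZ <- function(sym) {
  tab <- c(He = 2, Li = 3, Be = 4, B = 5, F = 9, Ne = 10, Na = 11, Mg = 12,
           Al = 13, Si = 14, Cl = 17, Ar = 18, K = 19, Ca = 20, Ti = 22,
           V = 23, Cr = 24, Mn = 25, Co = 27, Ni = 28, Cu = 29, Zn = 30,
           Se = 34, Br = 35, Mo = 42, I = 53, W = 74)
  if (sym %in% names(tab)) tab[[sym]] else 16
}

#' Water-shell specification
#'
#' @param thickness shell thickness T_w, Angstrom.
#' @param numberDensity waters per cubic Angstrom (default bulk, 0.0334).
#' @param contactDistance closest approach to solute atoms (default 2.8 A).
#' @param minSeparation minimum water-water distance (default 2.8 A).
#' @param seed placement seed.
#' @return a \linkS4class{WaterShellSpec}.
#' @export
waterShellSpec <- function(thickness, numberDensity = 0.0334,
                           contactDistance = 2.8, minSeparation = 2.8,
                           seed = 1) {
  new("WaterShellSpec", thickness = as.numeric(thickness),
      numberDensity = numberDensity, contactDistance = contactDistance,
      minSeparation = minSeparation, seed = as.integer(seed))
}

#' Surround a structure with a water shell of thickness T_w
#'
#' Adds one effective scatterer per water molecule (\code{"HOH"},
#' \eqn{f = f_O + 2 f_H}) by sequential dart-throwing into the region
#' whose distance to the nearest solute atom lies in
#' [contact, contact + T_w], honouring the minimum water-water
#' separation.  T_w = 0 returns the input unchanged.  The attempt budget
#' is sized so the achieved density approaches the requested bulk value.
#'
#' @param structure an \linkS4class{AtomicStructure}.
#' @param spec a \linkS4class{WaterShellSpec}.
#' @return the hydrated \linkS4class{AtomicStructure} (not re-centred:
#'   solute coordinates are preserved).
#' @export
addWaterShell <- function(structure, spec) {
  stopifnot(is(structure, "AtomicStructure"), is(spec, "WaterShellSpec"))
  if (spec@thickness == 0) return(structure)
  solute <- structure@positions[structure@elements != "HOH", , drop = FALSE]
  box <- apply(solute, 2, range)
  vbox <- prod(box[2, ] - box[1, ] + 2 * (spec@contactDistance + spec@thickness))
  nAttempts <- as.integer(min(8e6, ceiling(60 * spec@numberDensity * vbox)))
  old <- .Random.seed_exists()
  set.seed(spec@seed)
  w <- cpp_place_waters(solute, spec@contactDistance, spec@thickness,
                        spec@minSeparation, nAttempts, spec@numberDensity)
  .restore_seed(old)
  new("AtomicStructure",
      elements = c(structure@elements, rep("HOH", nrow(w))),
      positions = rbind(structure@positions, w),
      occupancy = c(structure@occupancy, rep(1, nrow(w))))
}

#' Spiky SASE-like temporal pulse profile
#'
#' Random spike intensities (gamma multipliers) under a Gaussian envelope
#' whose full duration at half maximum is \code{fdhm}, binned at
#' \code{binWidth}; fractions are normalized to sum 1.  The profile
#' mimics the stochastic spiky structure of self-amplified spontaneous
#' emission pulses; it is not a physical FEL simulation.
#'
#' @param nBins number of time bins.
#' @param fdhm envelope full duration at half maximum, fs (default 9).
#' @param seed integer seed.
#' @param binWidth bin width in fs (default 2.6).
#' @param spikeShape gamma shape of the per-bin intensity multipliers;
#'   smaller is spikier (default 6).
#' @return a \linkS4class{PulseProfile}.
#' @export
makeSasePulse <- function(nBins = 8, fdhm = 9, seed = 1, binWidth = 2.6,
                          spikeShape = 6) {
  stopifnot(nBins >= 1)
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  tt <- (seq_len(nBins) - (nBins + 1) / 2) * binWidth
  if (nBins == 1L) {
    frac <- 1
  } else {
    sigma <- fdhm / (2 * sqrt(2 * log(2)))
    env <- exp(-tt^2 / (2 * sigma^2))
    spikes <- stats::rgamma(nBins, shape = spikeShape, rate = spikeShape)
    frac <- env * spikes
    frac <- frac / sum(frac)
  }
  .restore_seed(old)
  new("PulseProfile", binTimes = tt, binFractions = frac, binWidth = binWidth)
}

#' Measured full duration at half maximum of a pulse profile
#'
#' Linear interpolation of the first and last half-maximum crossings of
#' the binned profile.  For a single spiky realization this fluctuates
#' by a bin or two around the envelope value; averaging profiles over
#' seeds before measuring recovers the envelope FDHM.
#'
#' @param pulse a \linkS4class{PulseProfile} or a numeric profile
#'   vector.
#' @param binWidth bin width in fs (taken from the object if a
#'   \linkS4class{PulseProfile} is given).
#' @return FDHM in fs.
#' @export
pulseFDHM <- function(pulse, binWidth = 2.6) {
  if (is(pulse, "PulseProfile")) {
    f <- pulse@binFractions
    tt <- pulse@binTimes
    binWidth <- pulse@binWidth
  } else {
    f <- as.numeric(pulse)
    tt <- (seq_along(f) - (length(f) + 1) / 2) * binWidth
  }
  n <- length(f)
  if (n == 1L) return(binWidth)
  half <- max(f) / 2
  above <- which(f >= half)
  i0 <- above[1]; i1 <- above[length(above)]
  tlo <- if (i0 == 1L) tt[1] - binWidth / 2 else
    tt[i0 - 1] + (half - f[i0 - 1]) / (f[i0] - f[i0 - 1]) * binWidth
  thi <- if (i1 == n) tt[n] + binWidth / 2 else
    tt[i1] + (f[i1] - half) / (f[i1] - f[i1 + 1]) * binWidth
  thi - tlo
}

#' Parametric expansion/ionization damage trajectory
#'
#' For each pulse bin with cumulative prior dose \eqn{D}, atoms are
#' displaced radially from the centroid by the factor
#' \eqn{1 + \mathrm{expansionRate}\, D} and the per-atom effective
#' electron count is scaled by \eqn{\max(0, 1 -
#' \mathrm{ionizationRate}\, D)}.  \eqn{D} is the fraction of pulse
#' energy deposited before the bin, so the first snapshot is the
#' undamaged structure and zero rates reproduce it in every bin.
#'
#' @param structure undamaged \linkS4class{AtomicStructure}.
#' @param pulse a \linkS4class{PulseProfile}.
#' @param expansionRate fractional radial expansion per unit dose.
#' @param ionizationRate fractional electron loss per unit dose.
#' @return a \linkS4class{DamageTrajectory}.
#' @export
makeDamageTrajectory <- function(structure, pulse, expansionRate = 0,
                                 ionizationRate = 0) {
  stopifnot(expansionRate >= 0, ionizationRate >= 0)
  frac <- pulse@binFractions
  doses <- cumsum(c(0, frac))[seq_along(frac)]
  ctr <- colMeans(structure@positions)
  rel <- sweep(structure@positions, 2, ctr)
  snaps <- lapply(doses, function(D) {
    fac <- 1 + expansionRate * D
    sc <- pmax(0, 1 - ionizationRate * D)
    new("AtomicStructure", elements = structure@elements,
        positions = sweep(rel * fac, 2, ctr, "+"),
        occupancy = structure@occupancy * sc)
  })
  new("DamageTrajectory", snapshots = snaps, fractions = frac, doses = doses,
      expansionRate = expansionRate, ionizationRate = ionizationRate)
}

#' Radius of gyration (occupancy-weighted)
#' @param structure an \linkS4class{AtomicStructure}.
#' @return Rg in Angstrom.
#' @export
radiusOfGyration <- function(structure) {
  w <- structure@occupancy
  ctr <- colSums(structure@positions * w) / sum(w)
  rel <- sweep(structure@positions, 2, ctr)
  sqrt(sum(w * rowSums(rel^2)) / sum(w))
}

setMethod("show", "PulseProfile", function(object) {
  cat(sprintf("PulseProfile: %d bins x %.1f fs, measured FDHM %.1f fs\n",
              length(object@binFractions), object@binWidth, pulseFDHM(object)))
})

setMethod("show", "DamageTrajectory", function(object) {
  cat(sprintf(
    "DamageTrajectory: %d snapshots, expansion %.3g, ionization %.3g\n",
    length(object@snapshots), object@expansionRate, object@ionizationRate))
})
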