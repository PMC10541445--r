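# Forward model: ideal reciprocal-space intensity volumes, Ewald-sphere
# slicing at arbitrary orientation, time integration over a damage
# trajectory, photon-budget scaling and Poisson sampling.
#
# Orientation convention: a pattern taken at orientation Omega samples the
# reference-frame intensity at R(Omega) q_t.  Equivalently, rotating the
# structure by R produces the pattern of orientation R^{-1} Omega.

#' Construct an intensity volume
#' @param values edge^3 numeric array (or vector), non-negative.
#' @param edge odd voxel count per axis (required if values is a vector).
#' @param dq voxel size, Angstrom^-1.
#' @param provenance optional provenance list.
#' @return an \linkS4class{IntensityVolume}.
#' @export
intensityVolume <- function(values, dq, edge = NULL, provenance = list()) {
  if (is.null(dim(values))) {
    stopifnot(!is.null(edge))
    values <- array(values, dim = c(edge, edge, edge))
  }
  new("IntensityVolume", values = values, dq = as.numeric(dq),
      provenance = provenance)
}

#' Volume edge length (voxels per axis)
#' @param volume an \linkS4class{IntensityVolume}.
#' @return integer edge length.
#' @export
volumeEdge <- function(volume) dim(volume@values)[1]

#' |q| of every voxel
#' @param volume an \linkS4class{IntensityVolume}.
#' @return numeric array of voxel |q| values, Angstrom^-1.
#' @export
volumeQmag <- function(volume) {
  e <- volumeEdge(volume)
  c0 <- (e - 1) / 2
  ax <- (seq_len(e) - 1 - c0) * volume@dq
  g <- expand.grid(x = ax, y = ax, z = ax)
  array(sqrt(g$x^2 + g$y^2 + g$z^2), dim = c(e, e, e))
}

setMethod("show", "IntensityVolume", function(object) {
  e <- volumeEdge(object)
  cat(sprintf(
    "IntensityVolume: %d^3 voxels, dq = %.5f A^-1 (|q| <= %.4f on axis)\n",
    e, object@dq, (e - 1) / 2 * object@dq))
})

#' Default volume gridding for a detector
#'
#' The voxel size equals the central pixel q-pitch and the edge is the
#' smallest odd count that contains the full Ewald cap out to the
#' detector-corner |q| under arbitrary rotation.
#'
#' @param geom a \linkS4class{DetectorGeometry}.
#' @return list with elements \code{edge} and \code{dq}.
#' @export
defaultVolumeGrid <- function(geom) {
  lam <- wavelength(geom)
  pitch_mm <- geom@pixelSize / 1000
  dq <- 2 * sin(atan2(pitch_mm, geom@distance) / 2) / lam
  qc <- cornerQ(geom)
  list(edge = as.integer(2 * ceiling(qc / dq) + 1), dq = dq)
}

#' Ideal reciprocal-space intensity of a structure
#'
#' Computes \eqn{I(q) = |\sum_j s_j f_j(|q|)\exp(2\pi i\, q\cdot r_j)|^2}
#' on a cubic grid (arbitrary overall scale).  For real scatterers the
#' result obeys Friedel symmetry \eqn{I(q) = I(-q)}.
#'
#' @param structure an \linkS4class{AtomicStructure}.
#' @param edge odd voxel count per axis.
#' @param dq voxel size, Angstrom^-1.
#' @return an \linkS4class{IntensityVolume}.
#' @export
idealIntensityVolume <- function(structure, edge, dq) {
  stopifnot(is(structure, "AtomicStructure"))
  edge <- as.integer(edge)
  if (edge %% 2L == 0L) stop("edge must be odd")
  fp <- .ffPack(structure@elements)
  v <- cpp_ideal_volume(structure@positions, structure@occupancy, fp$idx,
                        fp$ff, edge, dq)
  intensityVolume(v, dq, edge)
}

#' Time-integrated intensity volume of a damage trajectory
#'
#' The detector integrates over the whole pulse, so the expected pattern
#' is the pulse-fraction-weighted sum of the per-snapshot intensities;
#' this function returns that effective volume (and optionally the
#' per-bin volumes).
#'
#' @param trajectory a \linkS4class{DamageTrajectory}.
#' @param edge,dq grid parameters as in \code{\link{idealIntensityVolume}}.
#' @param perBin if TRUE also return the list of per-bin volumes.
#' @return an \linkS4class{IntensityVolume}, or a list
#'   \code{(total, bins)} when \code{perBin = TRUE}.
#' @export
timeIntegratedVolume <- function(trajectory, edge, dq, perBin = FALSE) {
  stopifnot(is(trajectory, "DamageTrajectory"))
  vols <- lapply(trajectory@snapshots, idealIntensityVolume, edge = edge,
                 dq = dq)
  tot <- Reduce(`+`, Map(function(v, f) v@values * f, vols,
                         trajectory@fractions))
  total <- intensityVolume(tot, dq, as.integer(edge))
  if (perBin) list(total = total, bins = vols) else total
}

# pixel q vectors in voxel units for a volume
.qcoords <- function(pixmap, volume) {
  need <- max(pixmap@qmag) / volume@dq
  if (need > (volumeEdge(volume) - 1) / 2)
    stop("pixel |q| outside volume support")
  pixmap@q / volume@dq
}

#' Expected intensity on the Ewald sphere at one orientation
#'
#' Evaluates the oriented intensity on the Ewald-mapped pixel q vectors,
#' either exactly from atoms or by trilinear interpolation in an
#' \linkS4class{IntensityVolume}.
#'
#' @param object an \linkS4class{AtomicStructure},
#'   \linkS4class{DamageTrajectory} (pulse-weighted sum of snapshots) or
#'   \linkS4class{IntensityVolume}.
#' @param orientation unit quaternion.
#' @param pixmap a \linkS4class{PixelMap}.
#' @return numeric vector of expected intensities per pixel (arbitrary
#'   scale).
#' @export
slicePattern <- function(object, orientation, pixmap) {
  quats <- matrix(orientation, 1)
  if (is(object, "IntensityVolume")) {
    drop(cpp_expand(as.vector(object@values), volumeEdge(object),
                    .qcoords(pixmap, object), quats))
  } else if (is(object, "AtomicStructure")) {
    fp <- .ffPack(object@elements)
    drop(cpp_slice_atoms(object@positions, object@occupancy, fp$idx, fp$ff,
                         pixmap@q, quats))
  } else if (is(object, "DamageTrajectory")) {
    out <- 0
    for (b in seq_along(object@fractions))
      out <- out + object@fractions[b] *
        slicePattern(object@snapshots[[b]], orientation, pixmap)
    out
  } else stop("unsupported object class: ", class(object))
}

# expected pixel intensities rescaled to a photon budget with an isotropic
# background fraction
.expectationToBudget <- function(expected, meanPhotons, background) {
  npix <- length(expected)
  s <- sum(expected)
  if (s <= 0) stop("zero expected intensity")
  (1 - background) * meanPhotons * expected / s +
    background * meanPhotons / npix
}

#' Simulate one photon-sparse diffraction pattern
#'
#' Expected pixel intensity (time-integrated over the trajectory if one
#' is given) plus an isotropic background, rescaled so the expectation
#' sums to \code{meanPhotons} over the detector, then Poisson sampled.
#'
#' @inheritParams slicePattern
#' @param meanPhotons expected total photons per pattern.
#' @param seed integer seed for the Poisson draw.
#' @param background fraction of the photon budget in the isotropic
#'   (inelastic stand-in) background, in [0, 1).
#' @return list with \code{counts} (integer per pixel), \code{expected}
#'   (the Poisson means) and \code{orientation}.
#' @export
simulatePattern <- function(object, orientation, pixmap, meanPhotons = 500,
                            seed = 1, background = 0) {
  stopifnot(meanPhotons > 0, background >= 0, background < 1)
  mu <- .expectationToBudget(slicePattern(object, orientation, pixmap),
                             meanPhotons, background)
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  counts <- stats::rpois(length(mu), mu)
  .restore_seed(old)
  list(counts = counts, expected = mu, orientation = orientation)
}

#' Generate a dataset of patterns at uniform random orientations
#'
#' Orientations are drawn uniformly on SO(3) (quaternions uniform on the
#' 3-sphere) from \code{seed} before any photon sampling, so two
#' conditions generated with the same seed share the identical
#' orientation list.  Patterns are stored sparsely in a
#' \linkS4class{PatternSet}.
#'
#' @param object structure, damage trajectory or intensity volume; a
#'   \emph{list} of such objects is cycled over patterns (ensemble of
#'   pulses/configurations), with the member index recorded in
#'   \code{structureId}.
#' @param nPatterns number of patterns (>= 1).
#' @param pixmap a \linkS4class{PixelMap}.
#' @param meanPhotons expected photons per pattern (default 500).
#' @param seed integer seed.
#' @param background isotropic background fraction in [0, 1).
#' @param orientations optional n x 4 quaternion matrix overriding the
#'   random draw.
#' @param role provenance tag, e.g. \code{"pattern"} or
#'   \code{"sentinel"}.
#' @param meta extra metadata list (water thickness, damage flag, ...).
#' @return a \linkS4class{PatternSet}.
#' @export
generateDataset <- function(object, nPatterns, pixmap, meanPhotons = 500,
                            seed = 1, background = 0, orientations = NULL,
                            role = "pattern", meta = list()) {
  if (nPatterns < 1) stop("nPatterns must be >= 1")
  objects <- if (is.list(object)) object else list(object)
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  if (is.null(orientations)) orientations <- randomRotations(nPatterns)
  npix <- nrow(pixmap@q)
  counts <- matrix(0L, npix, nPatterns)
  structureId <- rep(seq_along(objects), length.out = nPatterns)
  for (oi in seq_along(objects)) {
    idx <- which(structureId == oi)
    if (!length(idx)) next
    ob <- objects[[oi]]
    if (is(ob, "IntensityVolume")) {
      mu <- cpp_expand(as.vector(ob@values), volumeEdge(ob),
                       .qcoords(pixmap, ob),
                       orientations[idx, , drop = FALSE])
    } else {
      mu <- vapply(idx, function(d)
        slicePattern(ob, orientations[d, ], pixmap), numeric(npix))
    }
    # fixed incident fluence: one global scale per object sets the
    # orientation-ensemble MEAN to the photon budget (per-pattern totals
    # fluctuate with orientation, as on a real detector)
    tot <- colSums(mu)
    if (mean(tot) <= 0) stop("zero expected intensity")
    sc <- (1 - background) * meanPhotons / mean(tot)
    for (k in seq_along(idx)) {
      m <- mu[, k] * sc + background * meanPhotons / npix
      counts[, idx[k]] <- stats::rpois(npix, m)
    }
  }
  .restore_seed(old)
  patternSet(counts, orientations, pixmap, meanPhotons = meanPhotons,
             background = background, seed = seed, role = role,
             structureId = structureId, meta = meta)
}

#' Construct a PatternSet
#'
#' @param counts integer matrix or sparse Matrix (pixels x patterns).
#' @param orientations n x 4 quaternions (true orientations) or NULL.
#' @param pixmap the shared \linkS4class{PixelMap}.
#' @param meanPhotons,background,seed generation metadata.
#' @param role per-set provenance role tag.
#' @param structureId optional per-pattern ensemble member index.
#' @param meta extra metadata list.
#' @return a \linkS4class{PatternSet}.
#' @export
patternSet <- function(counts, orientations, pixmap, meanPhotons = NA_real_,
                       background = 0, seed = NA_integer_, role = "pattern",
                       structureId = NULL, meta = list()) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  n <- ncol(counts)
  if (is.null(orientations))
    orientations <- matrix(NA_real_, n, 4)
  if (is.null(structureId)) structureId <- rep(1L, n)
  cd <- S4Vectors::DataFrame(qw = orientations[, 1], qx = orientations[, 2],
                             qy = orientations[, 3], qz = orientations[, 4],
                             role = rep(role, length.out = n),
                             structureId = structureId,
                             patternId = sprintf("p%06d", seq_len(n)))
  datasetId <- sprintf("ds-%s-%d-%d",
                       if (is.na(seed)) "x" else seed, n, nrow(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd,
    metadata = c(list(pixmap = pixmap, meanPhotons = meanPhotons,
                      background = background, seed = seed,
                      datasetId = datasetId), meta))
  new("PatternSet", se)
}

#' Sparse photon counts of a pattern set
#' @param ps a \linkS4class{PatternSet}.
#' @return a dgCMatrix (pixels x patterns).
#' @export
patternCounts <- function(ps) SummarizedExperiment::assay(ps, "counts")

#' True orientations stored with a pattern set
#' @param ps a \linkS4class{PatternSet}.
#' @return n x 4 quaternion matrix (NA rows when unknown).
#' @export
trueOrientations <- function(ps) {
  cd <- SummarizedExperiment::colData(ps)
  unname(cbind(cd$qw, cd$qx, cd$qy, cd$qz))
}

#' Pixel map stored with a pattern set
#' @param ps a \linkS4class{PatternSet}.
#' @return the \linkS4class{PixelMap}.
#' @export
patternPixelMap <- function(ps) S4Vectors::metadata(ps)$pixmap

#' Dataset identifier (provenance tag)
#' @param ps a \linkS4class{PatternSet}.
#' @return character id.
#' @export
datasetId <- function(ps) S4Vectors::metadata(ps)$datasetId

setMethod("show", "PatternSet", function(object) {
  ct <- patternCounts(object)
  cat(sprintf(
    "PatternSet: %d patterns x %d pixels, mean %.1f photons/pattern (role %s)\n",
    ncol(ct), nrow(ct), mean(Matrix::colSums(ct)),
    paste(unique(SummarizedExperiment::colData(object)$role), collapse = "/")))
})
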