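# Reconstruction-quality metrics: shell R-factor, volume alignment, Poisson
# orientation posteriors and the orientation-disconcurrence (OD) metric on
# the symmetry quotient of SO(3).

#' Shell specification
#'
#' @param edges strictly increasing q bin edges (Angstrom^-1); NULL
#'   derives one-voxel-wide shells from the volume passed to
#'   \code{\link{shellRFactor}}.
#' @param regionBreaks the two boundaries of the named regions
#'   A (q < first), B (first <= q < second), C (q >= second); defaults
#'   0.08 and 0.10 Angstrom^-1.
#' @return a \linkS4class{ShellSpec}.
#' @export
shellSpec <- function(edges = NULL, regionBreaks = c(0.08, 0.10)) {
  if (is.null(edges)) edges <- numeric(0)
  new("ShellSpec", edges = edges, regionBreaks = regionBreaks)
}

#' Shell R-factor between a reconstruction and an ideal reference
#'
#' Per q shell \eqn{s},
#' \deqn{R(s) = \sum_{q \in s}\left|
#'   \frac{\sqrt{I(q)}}{\sum_{q' \in s}\sqrt{I(q')}} -
#'   \frac{\sqrt{I_{ideal}(q)}}{\sum_{q' \in s}\sqrt{I_{ideal}(q')}}
#'   \right|,}
#' a scale-free measure in [0, 2] (0 for proportional intensities, 2 for
#' disjoint support).  Region means over A/B/C are voxel-weighted.
#'
#' @param volume reconstructed \linkS4class{IntensityVolume}.
#' @param reference ideal \linkS4class{IntensityVolume} on the same grid.
#' @param shells a \linkS4class{ShellSpec}; default one-voxel-wide
#'   shells out to the inscribed-sphere radius.
#' @return a \linkS4class{ShellRFactorResult}.
#' @export
shellRFactor <- function(volume, reference, shells = shellSpec()) {
  stopifnot(is(volume, "IntensityVolume"), is(reference, "IntensityVolume"))
  if (volumeEdge(volume) != volumeEdge(reference) ||
      abs(volume@dq - reference@dq) > 1e-12 * volume@dq)
    stop("grid mismatch between volume and reference")
  qm <- as.vector(volumeQmag(volume))
  edges <- shells@edges
  if (!length(edges)) {
    qlim <- (volumeEdge(volume) - 1) / 2 * volume@dq
    edges <- seq(0, qlim + volume@dq, by = volume@dq)
  }
  keep <- qm >= edges[1] & qm < edges[length(edges)]
  bin <- findInterval(qm[keep], edges, rightmost.closed = FALSE)
  sI <- sqrt(as.vector(volume@values)[keep])
  sJ <- sqrt(as.vector(reference@values)[keep])
  nsh <- length(edges) - 1L
  R <- rep(NA_real_, nsh)
  nvox <- tabulate(bin, nbins = nsh)
  sumI <- rowsum(sI, bin)
  sumJ <- rowsum(sJ, bin)
  si <- numeric(nsh); sj <- numeric(nsh)
  si[as.integer(rownames(sumI))] <- sumI[, 1]
  sj[as.integer(rownames(sumJ))] <- sumJ[, 1]
  ok <- nvox > 0 & si > 0 & sj > 0
  if (any(nvox > 0 & !ok))
    warning("skipping ", sum(nvox > 0 & !ok), " shell(s) with zero intensity")
  dev <- abs(sI / si[bin] - sJ / sj[bin])
  dev[!ok[bin]] <- NA
  Rsum <- rowsum(dev, bin, na.rm = TRUE)
  R[as.integer(rownames(Rsum))] <- Rsum[, 1]
  R[!ok] <- NA
  qmid <- (edges[-1] + edges[-length(edges)]) / 2
  shellsDf <- data.frame(qlo = edges[-length(edges)], qhi = edges[-1],
                         qmid = qmid, nvox = nvox, R = R)
  rb <- shells@regionBreaks
  region <- cut(qmid, c(-Inf, rb, Inf), labels = c("A", "B", "C"))
  rm <- vapply(levels(region), function(g) {
    sel <- region == g & ok
    if (!any(sel)) return(NA_real_)
    sum(R[sel] * nvox[sel]) / sum(nvox[sel])
  }, numeric(1))
  new("ShellRFactorResult", shells = shellsDf, regionMeans = rm)
}

setMethod("show", "ShellRFactorResult", function(object) {
  cat(sprintf(
    "ShellRFactorResult: %d shells; region means A %.3f | B %.3f | C %.3f\n",
    sum(!is.na(object@shells$R)), object@regionMeans["A"],
    object@regionMeans["B"], object@regionMeans["C"]))
})

#' Align a volume to a reference by exhaustive rotation search
#'
#' Maximizes the Pearson correlation of square-root intensities between
#' the rotated-resampled volume and the reference, over a rotation
#' sample set followed by coordinate-wise golden-section refinement of
#' the three rotation parameters.
#'
#' @param volume,reference \linkS4class{IntensityVolume}s on one grid.
#' @param rotations a \linkS4class{RotationSet} of candidates (default
#'   level 3).
#' @param s,z optional symmetry groups whose elements extend the
#'   candidate list.
#' @param refineSteps golden-section sweeps (default 2).
#' @return list with \code{volume} (aligned), \code{rotation} (unit
#'   quaternion), \code{correlation}.
#' @export
alignToReference <- function(volume, reference, rotations = sampleRotations(3),
                             s = NULL, z = NULL, refineSteps = 2L) {
  if (volumeEdge(volume) != volumeEdge(reference) ||
      abs(volume@dq - reference@dq) > 1e-12 * volume@dq)
    stop("grid mismatch")
  e <- volumeEdge(volume)
  c0 <- (e - 1) / 2
  ax <- seq_len(e) - 1 - c0
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  rad <- sqrt(rowSums(g^2))
  mask <- rad > 0 & rad <= c0 - 1  # stay inside the support under rotation
  coords <- g[mask, , drop = FALSE]
  sqrtRef <- sqrt(pmax(as.vector(reference@values)[mask], 0))
  quats <- if (is(rotations, "RotationSet")) rotations@quaternions else rotations
  if (!is.null(s)) quats <- .expandByGroup(quats, s)
  if (!is.null(z)) quats <- .expandByGroup(quats, z)
  vol <- as.vector(volume@values)
  cors <- cpp_align_corr(vol, e, coords, sqrtRef, quats)
  best <- quats[which.max(cors), ]
  obj <- function(q) cpp_align_corr(vol, e, coords, sqrtRef, matrix(q, 1))[1]
  level <- if (is(rotations, "RotationSet")) rotations@level else 3L
  h <- 0.6 / max(1L, level)
  for (sweep in seq_len(refineSteps)) {
    for (axis in 1:3) {
      f <- function(d) {
        v <- c(0, 0, 0); v[axis] <- 1
        -obj(composeRotations(best, axisAngle(v, d)))
      }
      op <- stats::optimize(f, interval = c(-h, h))
      v <- c(0, 0, 0); v[axis] <- 1
      best <- composeRotations(best, axisAngle(v, op$minimum))
    }
    h <- h / 2
  }
  corr <- obj(best)
  aligned <- intensityVolume(cpp_rotate_volume(vol, e, best), volume@dq, e,
                             provenance = volume@provenance)
  list(volume = aligned, rotation = best, correlation = corr)
}

.expandByGroup <- function(quats, group) {
  stopifnot(is(group, "SymmetryGroup"))
  do.call(rbind, lapply(seq_len(nrow(group@elements)), function(i)
    canonicalizeQuat(quatMultiply(quats, group@elements[rep(i, nrow(quats)), ,
                                                        drop = FALSE]))))
}

#' Poisson log-likelihood of a pattern at a fixed orientation
#'
#' \eqn{\log p(K \mid \Omega; W) = \sum_t [K_t \ln W_{\Omega t} -
#' W_{\Omega t} - \ln K_t!]} with the \eqn{0 \ln 0 = 0} convention;
#' returns \code{-Inf} when a photon lands on a zero-intensity pixel.
#'
#' @param counts integer photon counts per pixel.
#' @param volume an \linkS4class{IntensityVolume} in expected-photon
#'   units.
#' @param orientation unit quaternion.
#' @param pixmap a \linkS4class{PixelMap}.
#' @return log-probability (scalar).
#' @export
patternLogLik <- function(counts, volume, orientation, pixmap) {
  if (any(counts < 0)) stop("negative counts")
  w <- slicePattern(volume, orientation, pixmap)
  pos <- counts > 0
  if (any(pos & w == 0)) return(-Inf)
  sum(counts[pos] * log(w[pos])) - sum(w) - sum(lfactorial(counts[pos]))
}

# posterior over a rotation grid from precomputed log-tomogram data
.posteriorFromTomo <- function(counts, logT, wsum, weights, epsilon,
                               maxSupport) {
  K <- methods::as(Matrix::Matrix(matrix(counts, ncol = 1), sparse = TRUE),
                   "CsparseMatrix")
  L <- cpp_spmm_ll(K@p, K@i, K@x, 1L, logT)
  lse <- cpp_softmax_cols(L, 1, log(weights) - wsum)
  p <- L[, 1]
  if (!all(is.finite(p))) stop("degenerate likelihood row")
  ord <- order(p, decreasing = TRUE)
  cum <- cumsum(p[ord])
  m <- which(cum >= 1 - epsilon)[1]
  if (is.na(m)) m <- length(ord)
  m <- min(m, maxSupport)
  idx <- ord[seq_len(m)]
  list(index = idx, prob = p[idx] / sum(p[idx]), full = p,
       logEvidence = lse[1])
}

#' Orientation posterior of a pattern over a rotation sample set
#'
#' Weight-multiplied Poisson likelihoods normalized over the rotation
#' samples (log-sum-exp stabilized), truncated to the smallest support
#' holding at least \eqn{1 - \epsilon} of the mass.
#'
#' @param counts integer photon counts per pixel.
#' @param volume an \linkS4class{IntensityVolume} (expected-photon
#'   units; use \code{normalizePhotons} to rescale to the pattern
#'   budget).
#' @param rotations a \linkS4class{RotationSet}.
#' @param pixmap a \linkS4class{PixelMap}.
#' @param epsilon truncation mass (default 1e-6).
#' @param maxSupport support size cap (default unlimited).
#' @param normalizePhotons rescale the volume so its mean tomogram
#'   photon sum matches \code{sum(counts)} before evaluating
#'   likelihoods (default TRUE).
#' @return list with \code{index} (support rotation indices),
#'   \code{prob} (truncated, renormalized posterior), \code{full} (the
#'   untruncated posterior) and \code{logEvidence}.
#' @export
orientationPosterior <- function(counts, volume, rotations, pixmap,
                                 epsilon = 1e-6, maxSupport = Inf,
                                 normalizePhotons = TRUE) {
  tomo <- expandVolume(volume, rotations, pixmap)
  if (normalizePhotons) {
    sc <- sum(counts) / mean(colSums(tomo))
    if (sc > 0) tomo <- tomo * sc
  }
  logT <- cpp_log_transpose(tomo, 1e-12)
  .posteriorFromTomo(counts, logT, colSums(tomo), rotations@weights, epsilon,
                     maxSupport)
}

#' Orientation-disconcurrence configuration
#'
#' @param level rotation refinement level of the posterior grid
#'   (default 4).
#' @param pointGroup particle point group s (default C1).
#' @param friedelGroup Friedel group z (default identity + pi about the
#'   beam axis).
#' @param epsilon posterior truncation mass (default 1e-6).
#' @param maxSupport per-sentinel support cap (default 256).
#' @param nCandidates full-objective evaluations of the best coarse
#'   candidates (default 8).
#' @param refineSteps golden-section sweeps (default 2).
#' @return an \linkS4class{ODConfig}.
#' @export
odConfig <- function(level = 4L, pointGroup = makeGroup("C1"),
                     friedelGroup = makeGroup("friedel_z"), epsilon = 1e-6,
                     maxSupport = 256L, nCandidates = 8L, refineSteps = 2L) {
  new("ODConfig", level = as.integer(level), pointGroup = pointGroup,
      friedelGroup = friedelGroup, epsilon = epsilon,
      maxSupport = as.integer(maxSupport), nCandidates = as.integer(nCandidates),
      refineSteps = as.integer(refineSteps))
}

# ragged support stacking for the C++ double-sum kernel
.stackSupports <- function(posts, quats) {
  off <- c(0L, cumsum(vapply(posts, function(p) length(p$index), integer(1))))
  q <- do.call(rbind, lapply(posts, function(p)
    quats[p$index, , drop = FALSE]))
  w <- unlist(lapply(posts, `[[`, "prob"), use.names = FALSE)
  list(q = q, w = w, off = as.integer(off))
}

#' Posterior-weighted squared orientation disagreement of one pattern
#'
#' The double integral of the squared quotient distance between the two
#' shifted orientation posteriors of a single pattern, discretized on
#' the rotation sample set (truncated supports).
#'
#' @param counts photon counts of the pattern.
#' @param volumeA,volumeB the two intensity volumes.
#' @param omegaA,omegaB overall orientations applied to the two volumes.
#' @param rotations a \linkS4class{RotationSet}.
#' @param s,z point group and Friedel group.
#' @param pixmap a \linkS4class{PixelMap}.
#' @param epsilon,maxSupport truncation controls.
#' @return squared angle (rad^2).
#' @export
thetaSq <- function(counts, volumeA, volumeB, omegaA = identityRotation(),
                    omegaB = identityRotation(), rotations, s = makeGroup("C1"),
                    z = makeGroup("C1"), pixmap, epsilon = 1e-6,
                    maxSupport = Inf) {
  pA <- orientationPosterior(counts, volumeA, rotations, pixmap, epsilon,
                             maxSupport)
  pB <- orientationPosterior(counts, volumeB, rotations, pixmap, epsilon,
                             maxSupport)
  quats <- rotations@quaternions
  qB <- canonicalizeQuat(quatMultiply(quats[pB$index, , drop = FALSE],
                                      matrix(invertRotation(omegaB), 1)))
  sA <- list(q = quats[pA$index, , drop = FALSE], w = pA$prob,
             off = c(0L, length(pA$index)))
  sB <- list(q = qB, w = pB$prob, off = c(0L, length(pB$index)))
  th <- cpp_theta_sq(matrix(invertRotation(omegaA), 1), sA$q, sA$w, sA$off,
                     sB$q, sB$w, sB$off, s@elements, z@elements)
  th[1, 1]
}

#' Orientation disconcurrence between two intensity volumes
#'
#' Decodes every sentinel pattern against both volumes (Poisson
#' orientation posteriors on a rotation sample grid), forms the
#' posterior-weighted mean squared quotient distance per sentinel, and
#' minimizes its sentinel average over the unknown overall orientation
#' between the volumes (one orientation is absorbed by bi-invariance;
#' the search runs over a coarse grid followed by golden-section
#' refinement).  \code{volumeB = NULL} computes the self-OD.
#'
#' @param volumeA,volumeB \linkS4class{IntensityVolume}s; NULL volumeB
#'   means self-OD.
#' @param sentinels a \linkS4class{PatternSet} of held-out patterns.
#' @param config an \linkS4class{ODConfig}.
#' @param override allow sentinels that overlap the reconstruction
#'   inputs (with a warning).
#' @param verbose print progress.
#' @return an \linkS4class{ODResult}.
#' @export
disconcurrence <- function(volumeA, volumeB = NULL, sentinels,
                           config = odConfig(), override = FALSE,
                           verbose = FALSE) {
  stopifnot(is(volumeA, "IntensityVolume"), is(sentinels, "PatternSet"))
  .checkSentinelLeakage(volumeA, sentinels, override)
  if (!is.null(volumeB)) .checkSentinelLeakage(volumeB, sentinels, override)
  selfOD <- is.null(volumeB)
  pixmap <- patternPixelMap(sentinels)
  rs <- sampleRotations(config@level)
  K <- patternCounts(sentinels)
  nsent <- ncol(K)
  if (nsent == 0L) stop("empty sentinel set")
  meanCounts <- mean(Matrix::colSums(K))
  postFor <- function(volume) {
    tomo <- expandVolume(volume, rs, pixmap)
    tomo <- tomo * (meanCounts / mean(colSums(tomo)))
    logT <- cpp_log_transpose(tomo, 1e-12)
    wsum <- colSums(tomo)
    lapply(seq_len(nsent), function(d)
      .posteriorFromTomo(K[, d], logT, wsum, rs@weights, config@epsilon,
                         config@maxSupport))
  }
  postA <- postFor(volumeA)
  postB <- if (selfOD) postA else postFor(volumeB)
  sA <- .stackSupports(postA, rs@quaternions)
  sB <- .stackSupports(postB, rs@quaternions)
  sQ <- config@pointGroup@elements
  zQ <- config@friedelGroup@elements
  # stage 1: coarse scan of the overall orientation using MAP-only supports
  mapA <- do.call(rbind, lapply(postA, function(p)
    rs@quaternions[p$index[1], ]))
  mapB <- do.call(rbind, lapply(postB, function(p)
    rs@quaternions[p$index[1], ]))
  offMap <- as.integer(0:nsent)
  w1 <- rep(1, nsent)
  coarse <- cpp_theta_sq(rs@quaternions, mapA, w1, offMap, mapB, w1, offMap,
                         sQ, zQ)
  coarseMean <- rowMeans(coarse)
  top <- order(coarseMean)[seq_len(min(config@nCandidates, length(coarseMean)))]
  full <- cpp_theta_sq(rs@quaternions[top, , drop = FALSE], sA$q, sA$w, sA$off,
                       sB$q, sB$w, sB$off, sQ, zQ)
  fullMean <- rowMeans(full)
  best <- rs@quaternions[top[which.min(fullMean)], ]
  objective <- function(q) {
    th <- cpp_theta_sq(matrix(q, 1), sA$q, sA$w, sA$off, sB$q, sB$w, sB$off,
                       sQ, zQ)
    mean(th[1, ])
  }
  h <- 0.6 / config@level
  for (sweep in seq_len(config@refineSteps)) {
    for (axis in 1:3) {
      f <- function(d) {
        v <- c(0, 0, 0); v[axis] <- 1
        objective(composeRotations(best, axisAngle(v, d)))
      }
      op <- stats::optimize(f, interval = c(-h, h))
      v <- c(0, 0, 0); v[axis] <- 1
      best <- composeRotations(best, axisAngle(v, op$minimum))
    }
    h <- h / 2
  }
  thBest <- cpp_theta_sq(matrix(best, 1), sA$q, sA$w, sA$off, sB$q, sB$w,
                         sB$off, sQ, zQ)[1, ]
  if (verbose)
    message(sprintf("OD: %d sentinels, level %d, delta-theta %.4f rad",
                    nsent, config@level, sqrt(mean(thBest))))
  new("ODResult", deltaTheta = sqrt(mean(thBest)),
      perSentinelTheta = sqrt(pmax(thBest, 0)),
      optimalOrientation = invertRotation(best))
}

.checkSentinelLeakage <- function(volume, sentinels, override) {
  prov <- volume@provenance
  if (is.null(prov$datasetId)) return(invisible(NULL))
  if (identical(prov$datasetId, datasetId(sentinels))) {
    ids <- SummarizedExperiment::colData(sentinels)$patternId
    if (length(intersect(prov$patternIds, ids))) {
      msg <- "sentinel patterns overlap the reconstruction inputs"
      if (override) warning(msg) else stop(msg)
    }
  }
  invisible(NULL)
}

setMethod("show", "ODResult", function(object) {
  cat(sprintf(
    "ODResult: delta-theta %.4f rad over %d sentinels (min %.4f, max %.4f)\n",
    object@deltaTheta, length(object@perSentinelTheta),
    min(object@perSentinelTheta), max(object@perSentinelTheta)))
})
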