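# Expand-maximize-compress reconstruction of the 3D reciprocal-space
# intensity from unoriented photon-sparse patterns, with tempered
# responsibilities (beta) and a growing rotation refinement level (num_div).

#' EMC configuration
#'
#' Defaults follow the production annealing schedule: start at
#' beta = 0.01 and rotation level 5, multiply beta by 1.5 and increase
#' the level by 1 every 10 iterations (level capped at \code{numDivCap},
#' beta at 1) for 120 main iterations, then run 10 final iterations at
#' beta = 1 and level 16.  Desk-scale runs lower \code{numDivCap},
#' \code{mainIterations} and \code{volumeEdge}.
#'
#' @param betaStart initial tempering factor in (0, 1].
#' @param betaFactor multiplicative beta growth per period.
#' @param betaPeriod iterations between schedule updates.
#' @param numDivStart,numDivStep,numDivCap rotation refinement schedule.
#' @param mainIterations,finalIterations schedule phase lengths.
#' @param finalNumDiv rotation level of the final phase (defaults to
#'   \code{min(16, numDivCap)}).
#' @param volumeEdge odd voxel count of the reconstruction grid; NA
#'   chooses the detector-matched grid of
#'   \code{\link{defaultVolumeGrid}}.
#' @param initSeed seed for the random initial volume.
#' @param tomoFloor intensity floor used inside logarithms.
#' @return an \linkS4class{EMCConfig}.
#' @export
emcConfig <- function(betaStart = 0.01, betaFactor = 1.5, betaPeriod = 10L,
                      numDivStart = 5L, numDivStep = 1L, numDivCap = 16L,
                      mainIterations = 120L, finalIterations = 10L,
                      finalNumDiv = NA_integer_, volumeEdge = NA_integer_,
                      initSeed = 1L, tomoFloor = 1e-10) {
  if (is.na(finalNumDiv)) finalNumDiv <- min(16L, as.integer(numDivCap))
  new("EMCConfig", betaStart = betaStart, betaFactor = betaFactor,
      betaPeriod = as.integer(betaPeriod), numDivStart = as.integer(numDivStart),
      numDivStep = as.integer(numDivStep), numDivCap = as.integer(numDivCap),
      mainIterations = as.integer(mainIterations),
      finalIterations = as.integer(finalIterations),
      finalNumDiv = as.integer(finalNumDiv),
      volumeEdge = as.integer(volumeEdge), initSeed = as.integer(initSeed),
      tomoFloor = tomoFloor)
}

#' Desk-scale EMC preset
#'
#' A single-CPU-sized 30-iteration schedule: 10 main iterations from
#' (beta 0.01, level 5), capped at level 6, followed by 20 final
#' iterations at beta = 1 and level 6, on a 33^3 grid.  The long
#' final phase replaces the production schedule's slow beta ramp, which
#' at desk scale would end before the tempered responsibilities carry
#' any orientation information.
#' @param ... overrides passed to \code{\link{emcConfig}}.
#' @return an \linkS4class{EMCConfig}.
#' @export
emcConfigDesk <- function(...) {
  args <- list(numDivCap = 6L, mainIterations = 10L, finalIterations = 20L,
               volumeEdge = 33L)
  over <- list(...)
  args[names(over)] <- over
  do.call(emcConfig, args)
}

#' Beta / num_div schedule of an EMC configuration
#'
#' @param config an \linkS4class{EMCConfig}.
#' @return data.frame with columns iteration, beta, numDiv, phase.
#' @export
emcSchedule <- function(config) {
  it <- seq_len(config@mainIterations)
  step <- (it - 1) %/% config@betaPeriod
  beta <- pmin(1, config@betaStart * config@betaFactor^step)
  nd <- pmin(config@numDivCap, config@numDivStart + config@numDivStep * step)
  main <- data.frame(iteration = it, beta = beta, numDiv = as.integer(nd),
                     phase = "main")
  if (config@finalIterations > 0L) {
    fin <- data.frame(
      iteration = config@mainIterations + seq_len(config@finalIterations),
      beta = 1, numDiv = config@finalNumDiv, phase = "final")
    main <- rbind(main, fin)
  }
  main
}

#' Expand a model volume into per-rotation tomograms
#'
#' One expected-intensity tomogram per rotation sample, by trilinear
#' interpolation of the volume on the rotated Ewald pixel map.
#'
#' @param volume an \linkS4class{IntensityVolume}.
#' @param rotations a \linkS4class{RotationSet} (or quaternion matrix).
#' @param pixmap a \linkS4class{PixelMap}.
#' @return numeric matrix (pixels x rotations), non-negative.
#' @export
expandVolume <- function(volume, rotations, pixmap) {
  quats <- if (is(rotations, "RotationSet")) rotations@quaternions else rotations
  cpp_expand(as.vector(volume@values), volumeEdge(volume),
             .qcoords(pixmap, volume), quats)
}

#' Compress tomograms into a model volume
#'
#' Scatter-adjoint of \code{\link{expandVolume}}: each tomogram pixel
#' deposits its value into the neighbouring voxels with trilinear
#' weights; a voxel's value is the weighted mean of deposits, and voxels
#' never touched are 0.
#'
#' @param tomograms pixels x rotations matrix.
#' @param rotations a \linkS4class{RotationSet} (or quaternion matrix).
#' @param pixmap a \linkS4class{PixelMap}.
#' @param dq,edge target grid.
#' @return an \linkS4class{IntensityVolume}.
#' @export
compressTomograms <- function(tomograms, rotations, pixmap, dq, edge) {
  quats <- if (is(rotations, "RotationSet")) rotations@quaternions else rotations
  cm <- cpp_compress(tomograms, as.integer(edge), pixmap@q / dq, quats)
  vals <- ifelse(cm$wt > 1e-12, cm$num / pmax(cm$wt, 1e-300), 0)
  intensityVolume(pmax(vals, 0), dq, as.integer(edge))
}

# core E+M step on prepared tomograms; K is the dgCMatrix of counts
.maximizeCore <- function(tomograms, K, beta, weights, floorVal,
                          wantResponsibilities = FALSE) {
  if (length(K@x) == 0L || sum(K@x) == 0) stop("all-zero pattern set")
  offset <- log(weights) - beta * colSums(tomograms)
  st <- cpp_emc_step(tomograms, K@p, K@i, K@x, ncol(K), beta, offset,
                     floorVal, wantResponsibilities)
  list(tomograms = st$tomograms, loglik = mean(st$ll) / beta,
       responsibilities = st$responsibilities, bestRotation = st$best,
       entropy = st$entropy)
}

#' One maximize (expectation-maximization) step
#'
#' Computes tempered responsibilities
#' \eqn{P_{dr} \propto w_r \exp(\beta\,\log p(K_d \mid r))} under the
#' per-pixel Poisson likelihood, and returns the responsibility-weighted
#' mean pattern per rotation as the updated tomogram set.
#'
#' @param tomograms pixels x rotations expected intensities (photon
#'   units).
#' @param patterns a \linkS4class{PatternSet}.
#' @param beta tempering factor in (0, 1].
#' @param weights rotation quadrature weights.
#' @param tomoFloor intensity floor inside logarithms.
#' @return list with updated \code{tomograms}, mean tempered
#'   log-likelihood \code{loglik}, per-pattern \code{bestRotation} index
#'   and responsibility \code{entropy}, and the responsibility matrix
#'   (rotations x patterns).
#' @export
maximizeStep <- function(tomograms, patterns, beta, weights,
                         tomoFloor = 1e-10) {
  stopifnot(beta > 0, beta <= 1)
  K <- patternCounts(patterns)
  .maximizeCore(tomograms, K, beta, weights, tomoFloor,
                wantResponsibilities = TRUE)
}

#' Run the EMC reconstruction
#'
#' Initializes the model volume from seeded uniform random positives
#' scaled to the data, then alternates expand, maximize and compress
#' along the beta / num_div schedule of \code{config}.  Deterministic
#' given the configuration seed.
#'
#' @param patterns a \linkS4class{PatternSet}.
#' @param config an \linkS4class{EMCConfig}.
#' @param verbose print one line per iteration.
#' @return an \linkS4class{EMCState}.
#' @export
runEMC <- function(patterns, config = emcConfig(), verbose = FALSE) {
  stopifnot(is(patterns, "PatternSet"))
  K <- patternCounts(patterns)
  pixmap <- patternPixelMap(patterns)
  meanCounts <- mean(Matrix::colSums(K))
  if (meanCounts <= 0) stop("all-zero pattern set")
  qmax <- max(pixmap@qmag)
  if (is.na(config@volumeEdge)) {
    dqc <- min(pixmap@qmag[pixmap@qmag > 0])
    edge <- as.integer(2 * ceiling(qmax / dqc) + 1)
    dq <- dqc
  } else {
    edge <- config@volumeEdge
    dq <- qmax / ((edge - 3) / 2)
  }
  sched <- emcSchedule(config)
  old <- .Random.seed_exists()
  set.seed(config@initSeed)
  vol <- intensityVolume(stats::runif(edge^3, 0.5, 1.5), dq, edge)
  .restore_seed(old)
  trace <- sched
  trace$meanLogLik <- NA_real_
  trace$seconds <- NA_real_
  best <- NULL; ent <- NULL; rs <- NULL
  for (i in seq_len(nrow(sched))) {
    t0 <- proc.time()[["elapsed"]]
    if (is.null(rs) || rs@level != sched$numDiv[i])
      rs <- sampleRotations(sched$numDiv[i])
    tomo <- expandVolume(vol, rs, pixmap)
    sc <- meanCounts / mean(colSums(tomo))
    tomo <- tomo * sc
    mx <- .maximizeCore(tomo, K, sched$beta[i], rs@weights, config@tomoFloor)
    vol <- compressTomograms(mx$tomograms, rs, pixmap, dq, edge)
    best <- mx$bestRotation; ent <- mx$entropy
    trace$meanLogLik[i] <- mx$loglik
    trace$seconds[i] <- proc.time()[["elapsed"]] - t0
    if (verbose)
      message(sprintf(
        "iter %3d  beta %.4f  num_div %2d  <loglik> %.3f  %.1fs",
        sched$iteration[i], sched$beta[i], sched$numDiv[i], mx$loglik,
        trace$seconds[i]))
  }
  vol@provenance <- list(datasetId = datasetId(patterns),
                         patternIds = SummarizedExperiment::colData(patterns)$patternId,
                         role = "emc-reconstruction")
  new("EMCState", volume = vol, trace = trace,
      bestOrientation = rs@quaternions[best, , drop = FALSE],
      orientationEntropy = ent)
}

setMethod("show", "EMCState", function(object) {
  n <- nrow(object@trace)
  cat(sprintf(
    "EMCState: %d iterations (final beta %.3g, num_div %d), <loglik> %.3f\n",
    n, object@trace$beta[n], object@trace$numDiv[n],
    object@trace$meanLogLik[n]))
})
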