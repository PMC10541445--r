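# Orchestration: condition scans over water-layer thickness and damage,
# repeated EMC reconstructions, metric aggregation and figure/table reports.

#' Construct an experiment plan
#'
#' @param waterThickness water-layer thicknesses T_w to scan, Angstrom
#'   (default the full scan 0, 2, 4, 6, 10, 20).
#' @param damage logical vector of damage conditions to scan (default
#'   FALSE only; \code{c(FALSE, TRUE)} scans both).
#' @param patternsPerCondition diffraction patterns per condition.
#' @param sentinelsPerCondition held-out sentinel patterns (default 500).
#' @param emcRepeats independent EMC reconstructions per condition
#'   (default 3).
#' @param meanPhotons expected photons per pattern (default 500).
#' @param background isotropic background fraction of the photon budget
#'   (inelastic-scattering stand-in; default 0.1).
#' @param seed master seed; every stage seed derives from it.
#' @param scale \code{"desk"} or \code{"full"} label (bookkeeping only;
#'   the numeric fields define the actual scale).
#' @param particle particle recipe: list with \code{type} ("toy" or
#'   "pdb"), toy fields \code{n}, \code{extent}, \code{symmetrize}, pdb
#'   field \code{path}, and damage stand-in fields \code{expansionRate},
#'   \code{ionizationRate}, \code{nPulses}, \code{pulseBins}.
#' @param emc an \linkS4class{EMCConfig}.
#' @param od an \linkS4class{ODConfig}.
#' @param geometry a \linkS4class{DetectorGeometry}.
#' @param odSource \code{"reconstruction"} (self-OD of each EMC volume,
#'   the production analysis) or \code{"groundTruth"} (self-OD of the
#'   ideal volume, repeat-independent).
#' @return an \linkS4class{ExperimentPlan}.
#' @export
experimentPlan <- function(waterThickness = c(0, 2, 4, 6, 10, 20),
                           damage = FALSE, patternsPerCondition = 20000L,
                           sentinelsPerCondition = 500L, emcRepeats = 3L,
                           meanPhotons = 500, background = 0.1, seed = 1L,
                           scale = "full",
                           particle = list(type = "toy", n = 40, extent = 100,
                                           symmetrize = FALSE,
                                           expansionRate = 0.2,
                                           ionizationRate = 0.3,
                                           nPulses = 5, pulseBins = 8),
                           emc = emcConfig(), od = odConfig(),
                           geometry = detectorGeometry(),
                           odSource = c("reconstruction", "groundTruth")) {
  odSource <- match.arg(odSource)
  new("ExperimentPlan", waterThickness = waterThickness,
      damage = as.logical(damage),
      patternsPerCondition = as.integer(patternsPerCondition),
      sentinelsPerCondition = as.integer(sentinelsPerCondition),
      emcRepeats = as.integer(emcRepeats), meanPhotons = meanPhotons,
      background = background, seed = as.integer(seed), scale = scale,
      particle = particle, emc = emc, od = od, geometry = geometry,
      odSource = odSource)
}

#' Desk-scale experiment preset
#'
#' Single-CPU scale: a 40-atom, 25-Angstrom toy particle (sized so the
#' 33^3 desk grid resolves its speckles with ~3 voxels each), a 41 x 41
#' pixel binned detector covering the same q range as the production
#' geometry, 2000 patterns and 50 sentinels per condition, one EMC
#' repeat with the desk EMC schedule, and T_w in \{0, 20\} Angstrom.
#'
#' @param ... overrides forwarded to \code{\link{experimentPlan}}.
#' @return an \linkS4class{ExperimentPlan}.
#' @export
deskPlan <- function(...) {
  args <- list(waterThickness = c(0, 20), damage = FALSE,
               patternsPerCondition = 2000L, sentinelsPerCondition = 50L,
               emcRepeats = 1L, scale = "desk", emc = emcConfigDesk(),
               od = odConfig(level = 4L),
               particle = list(type = "toy", n = 40, extent = 25,
                               symmetrize = FALSE, expansionRate = 0.2,
                               ionizationRate = 0.3, nPulses = 5,
                               pulseBins = 8),
               geometry = detectorGeometry(nFast = 41L, nSlow = 41L,
                                           pixelSize = 2400))
  over <- list(...)
  args[names(over)] <- over
  do.call(experimentPlan, args)
}

#' Full-scale (production) experiment preset
#'
#' The production study design: T_w in \{0, 2, 4, 6, 10, 20\} Angstrom
#' with and without damage, 20000 patterns and 500 sentinels per
#' condition at ~500 photons each, 3 EMC repeats with the full
#' beta/num_div schedule (120 + 10 iterations, level up to 16) on the
#' 81 x 81 detector.  Cluster-scale; not intended for a single desktop
#' session.
#'
#' @param ... overrides forwarded to \code{\link{experimentPlan}}.
#' @return an \linkS4class{ExperimentPlan}.
#' @export
fullPlan <- function(...) {
  args <- list(waterThickness = c(0, 2, 4, 6, 10, 20),
               damage = c(FALSE, TRUE), patternsPerCondition = 20000L,
               sentinelsPerCondition = 500L, emcRepeats = 3L, scale = "full",
               emc = emcConfig(), od = odConfig(level = 8L),
               geometry = detectorGeometry())
  over <- list(...)
  args[names(over)] <- over
  do.call(experimentPlan, args)
}

# deterministic small sub-seed derivation (kept well below 2^31)
.subSeed <- function(seed, ...) {
  k <- c(...)
  as.integer((as.numeric(seed) * 2654435 + sum(k * seq_along(k) * 97003)) %%
               2147483647)
}

.buildParticle <- function(plan) {
  p <- plan@particle
  if (identical(p$type, "pdb")) {
    readPDBStructure(p$path)
  } else {
    makeToyParticle(n = p$n %||% 40, extent = p$extent %||% 100,
                    seed = plan@seed,
                    symmetrize = isTRUE(p$symmetrize))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reconstruction/ground-truth grid shared by all stages of a plan
.planGrid <- function(plan, pixmap) {
  qmax <- max(pixmap@qmag)
  edge <- plan@emc@volumeEdge
  if (is.na(edge)) {
    g <- defaultVolumeGrid(plan@geometry)
    list(edge = g$edge, dq = g$dq)
  } else {
    list(edge = as.integer(edge), dq = qmax / ((edge - 3) / 2))
  }
}

#' Run a condition-scan experiment
#'
#' For every condition (water thickness x damage flag): generate the
#' hydrated (optionally damaged) particle and its ground-truth intensity
#' volume, simulate pattern and sentinel sets, run \code{emcRepeats}
#' independent EMC reconstructions, align each to the ground truth, and
#' evaluate the shell R-factor and the self-OD.  Fully reproducible from
#' the plan; a failing condition is logged and skipped.
#'
#' @param plan an \linkS4class{ExperimentPlan}.
#' @param verbose print per-stage progress.
#' @return an \linkS4class{SPIReport}.
#' @export
runExperiment <- function(plan, verbose = FALSE) {
  stopifnot(is(plan, "ExperimentPlan"))
  pixmap <- buildPixelMap(plan@geometry)
  grid <- .planGrid(plan, pixmap)
  particle <- .buildParticle(plan)
  conds <- expand.grid(Tw = plan@waterThickness, damage = plan@damage)
  rows <- list(); shellTabs <- list(); slices <- list()
  for (ci in seq_len(nrow(conds))) {
    Tw <- conds$Tw[ci]; dmg <- conds$damage[ci]
    label <- sprintf("Tw%g%s", Tw, if (dmg) "_damage" else "")
    res <- tryCatch(
      .runCondition(plan, particle, pixmap, grid, Tw, dmg, verbose),
      error = function(e) {
        warning(sprintf("condition %s failed: %s", label, conditionMessage(e)))
        NULL
      })
    if (is.null(res)) next
    rows[[label]] <- data.frame(
      condition = label, Tw = Tw, damage = dmg,
      deltaThetaMean = mean(res$deltaTheta), deltaThetaSD = stats::sd(res$deltaTheta),
      RbarA = mean(res$regionMeans["A", ]), RbarB = mean(res$regionMeans["B", ]),
      RbarC = mean(res$regionMeans["C", ]),
      alignCorrMean = mean(res$alignCorr))
    shellTabs[[label]] <- res$shellTab
    slices[[label]] <- res$slices
  }
  if (!length(rows))
    return(new("SPIReport", conditions = data.frame(), shellR = list(),
               slices = list(),
               provenance = list(seed = plan@seed, scale = plan@scale)))
  new("SPIReport", conditions = do.call(rbind, c(rows, make.row.names = FALSE)),
      shellR = shellTabs, slices = slices,
      provenance = list(seed = plan@seed, scale = plan@scale,
                        patterns = plan@patternsPerCondition,
                        sentinels = plan@sentinelsPerCondition,
                        repeats = plan@emcRepeats,
                        meanPhotons = plan@meanPhotons,
                        background = plan@background,
                        grid = grid, odSource = plan@odSource,
                        version = as.character(utils::packageVersion("spiOrient"))))
}

.runCondition <- function(plan, particle, pixmap, grid, Tw, dmg, verbose) {
  if (verbose) message(sprintf("condition T_w = %g A, damage = %s", Tw, dmg))
  twIdx <- match(Tw, plan@waterThickness)
  hydrated <- addWaterShell(particle,
                            waterShellSpec(Tw, seed = .subSeed(plan@seed, 11, twIdx)))
  truth <- idealIntensityVolume(hydrated, grid$edge, grid$dq)
  truth@provenance <- list(role = "ground-truth", Tw = Tw)
  p <- plan@particle
  genObject <- if (dmg) {
    lapply(seq_len(p$nPulses %||% 5), function(k) {
      pulse <- makeSasePulse(nBins = p$pulseBins %||% 8, fdhm = 9,
                             seed = .subSeed(plan@seed, 23, k))
      traj <- makeDamageTrajectory(hydrated, pulse,
                                   expansionRate = p$expansionRate %||% 0.2,
                                   ionizationRate = p$ionizationRate %||% 0.3)
      timeIntegratedVolume(traj, grid$edge, grid$dq)
    })
  } else truth
  meta <- list(Tw = Tw, damage = dmg)
  patterns <- generateDataset(genObject, plan@patternsPerCondition, pixmap,
                              meanPhotons = plan@meanPhotons,
                              seed = plan@seed,
                              background = plan@background, meta = meta)
  sentinels <- generateDataset(genObject, plan@sentinelsPerCondition, pixmap,
                               meanPhotons = plan@meanPhotons,
                               seed = .subSeed(plan@seed, 7, twIdx, dmg),
                               background = plan@background,
                               role = "sentinel", meta = meta)
  deltaTheta <- numeric(0); alignCorr <- numeric(0)
  regionMeans <- NULL; shellCurves <- NULL; firstSlice <- NULL
  odTruth <- if (plan@odSource == "groundTruth")
    disconcurrence(truth, sentinels = sentinels, config = plan@od)
  else NULL
  for (r in seq_len(plan@emcRepeats)) {
    cfg <- plan@emc
    cfg@initSeed <- .subSeed(plan@seed, 31, twIdx, dmg, r)
    state <- runEMC(patterns, cfg, verbose = verbose)
    al <- alignToReference(state@volume, truth)
    alignCorr <- c(alignCorr, al$correlation)
    sr <- shellRFactor(al$volume, truth)
    regionMeans <- cbind(regionMeans, sr@regionMeans)
    shellCurves <- cbind(shellCurves, sr@shells$R)
    od <- if (is.null(odTruth))
      disconcurrence(state@volume, sentinels = sentinels, config = plan@od)
    else odTruth
    deltaTheta <- c(deltaTheta, od@deltaTheta)
    if (r == 1L) {
      e <- grid$edge; mid <- (e + 1) / 2
      firstSlice <- list(truth = truth@values[, , mid],
                         recon = al$volume@values[, , mid], dq = grid$dq)
    }
  }
  sr1 <- shellRFactor(truth, truth)  # shell axis template
  shellTab <- data.frame(qmid = sr1@shells$qmid,
                         Rmean = rowMeans(shellCurves, na.rm = TRUE),
                         Rsd = apply(shellCurves, 1, stats::sd))
  list(deltaTheta = deltaTheta, alignCorr = alignCorr,
       regionMeans = regionMeans, shellTab = shellTab, slices = firstSlice)
}

setMethod("show", "SPIReport", function(object) {
  cat(sprintf("SPIReport: %d condition(s)\n", nrow(object@conditions)))
  if (nrow(object@conditions)) print(object@conditions, digits = 3)
})

#' Write a report to JSON and TSV
#'
#' @param report an \linkS4class{SPIReport}.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonPath <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(schema = "spiOrient-report-1",
         conditions = report@conditions,
         provenance = report@provenance),
    jsonPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tsvPaths <- character(0)
  for (nm in names(report@shellR)) {
    p <- file.path(dir, sprintf("shellR_%s.tsv", nm))
    utils::write.table(report@shellR[[nm]], p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    tsvPaths <- c(tsvPaths, p)
  }
  condPath <- file.path(dir, "conditions.tsv")
  utils::write.table(report@conditions, condPath, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(jsonPath, condPath, tsvPaths))
}

#' Figure files from a report
#'
#' Writes three PNG files: central reciprocal-space slices with circles
#' at q = 0.08 and 0.10 Angstrom^-1, shell R-factor curves with the two
#' region boundaries marked, and the OD versus water-thickness curve
#' with error bars.
#'
#' @param report an \linkS4class{SPIReport}.
#' @param dir output directory.
#' @return invisibly, the paths written (character(0) for an empty
#'   report, with a warning).
#' @export
makeFigures <- function(report, dir) {
  if (!nrow(report@conditions)) {
    warning("empty report; no figures written")
    return(invisible(character(0)))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  # slices
  p1 <- file.path(dir, "slices.png")
  n <- length(report@slices)
  grDevices::png(p1, width = 400 * 2, height = 400 * n)
  graphics::par(mfrow = c(n, 2), mar = c(2, 2, 2, 1))
  for (nm in names(report@slices)) {
    sl <- report@slices[[nm]]
    for (what in c("truth", "recon")) {
      m <- log1p(sl[[what]])
      e <- nrow(m); c0 <- (e - 1) / 2
      ax <- (seq_len(e) - 1 - c0) * sl$dq
      graphics::image(ax, ax, m, col = grDevices::hcl.colors(64, "inferno"),
                      main = paste(nm, what), asp = 1, xlab = "", ylab = "")
      th <- seq(0, 2 * pi, length.out = 200)
      for (qc in c(0.08, 0.10))
        graphics::lines(qc * cos(th), qc * sin(th), col = "white", lty = 2)
    }
  }
  grDevices::dev.off()
  paths <- c(paths, p1)
  # shell R curves
  p2 <- file.path(dir, "shell_r.png")
  grDevices::png(p2, width = 700, height = 500)
  cols <- grDevices::hcl.colors(max(2, length(report@shellR)), "viridis")
  first <- TRUE
  i <- 1
  for (nm in names(report@shellR)) {
    tb <- report@shellR[[nm]]
    if (first) {
      graphics::plot(tb$qmid, tb$Rmean, type = "l", col = cols[i], ylim = c(0, 2),
                     xlab = "q (1/A)", ylab = "shell R-factor")
      first <- FALSE
    } else graphics::lines(tb$qmid, tb$Rmean, col = cols[i])
    i <- i + 1
  }
  graphics::abline(v = c(0.08, 0.10), lty = 2, col = "grey40")
  graphics::legend("topleft", legend = names(report@shellR), col = cols,
                   lty = 1, cex = 0.8)
  grDevices::dev.off()
  paths <- c(paths, p2)
  # OD vs Tw
  p3 <- file.path(dir, "od_vs_tw.png")
  grDevices::png(p3, width = 700, height = 500)
  cd <- report@conditions
  graphics::plot(cd$Tw, cd$deltaThetaMean, pch = 19,
                 col = ifelse(cd$damage, "firebrick", "steelblue"),
                 xlab = "water layer thickness (A)",
                 ylab = "self-OD delta-theta (rad)")
  graphics::arrows(cd$Tw, cd$deltaThetaMean - cd$deltaThetaSD, cd$Tw,
                   cd$deltaThetaMean + cd$deltaThetaSD, angle = 90, code = 3,
                   length = 0.04, col = "grey50")
  grDevices::dev.off()
  invisible(c(paths, p3))
}
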