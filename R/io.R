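# Plain-text serialization (TSV + JSON headers) for the package's data
# objects, and the YAML configuration reader.

#' Write an intensity volume to a TSV file
#'
#' Header lines (\code{# edge}, \code{# dq}) followed by one value per
#' line in column-major order.
#'
#' @param volume an \linkS4class{IntensityVolume}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeIntensityVolume <- function(volume, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# spiOrient-volume edge=%d dq=%.17g",
                       volumeEdge(volume), volume@dq)), con)
  writeLines(sprintf("%.10g", as.vector(volume@values)), con)
  invisible(path)
}

#' Read an intensity volume written by \code{\link{writeIntensityVolume}}
#' @param path input file.
#' @return an \linkS4class{IntensityVolume}.
#' @export
readIntensityVolume <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("edge=([0-9]+) dq=([0-9.eE+-]+)", hdr))[[1]]
  if (length(m) != 3) stop("not a spiOrient volume file")
  edge <- as.integer(m[2]); dq <- as.numeric(m[3])
  vals <- utils::read.table(path, skip = 1)[, 1]
  intensityVolume(vals, dq, edge)
}

#' Write a pattern set as TSV + JSON
#'
#' Creates \code{<prefix>_meta.json} (geometry, generation parameters),
#' \code{<prefix>_counts.tsv} (pattern, pixel, count triplets; 1-based)
#' and \code{<prefix>_orientations.tsv}.
#'
#' @param ps a \linkS4class{PatternSet}.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
writePatternSet <- function(ps, prefix) {
  K <- patternCounts(ps)
  md <- S4Vectors::metadata(ps)
  pm <- md$pixmap
  metaPath <- paste0(prefix, "_meta.json")
  jsonlite::write_json(
    list(schema = "spiOrient-patternset-1", nPixels = nrow(K),
         nPatterns = ncol(K), nFast = pm@nFast, nSlow = pm@nSlow,
         wavelength = pm@wavelength, meanPhotons = md$meanPhotons,
         background = md$background, seed = md$seed,
         datasetId = md$datasetId,
         role = as.character(SummarizedExperiment::colData(ps)$role[1]),
         qvec = list(qx = pm@q[, 1], qy = pm@q[, 2], qz = pm@q[, 3])),
    metaPath, auto_unbox = TRUE, digits = NA)
  tk <- Matrix::summary(K)
  countsPath <- paste0(prefix, "_counts.tsv")
  utils::write.table(data.frame(pattern = tk$j, pixel = tk$i,
                                count = as.integer(tk$x)),
                     countsPath, sep = "\t", row.names = FALSE, quote = FALSE)
  oriPath <- paste0(prefix, "_orientations.tsv")
  ori <- trueOrientations(ps)
  utils::write.table(data.frame(qw = ori[, 1], qx = ori[, 2], qy = ori[, 3],
                                qz = ori[, 4]),
                     oriPath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(metaPath, countsPath, oriPath))
}

#' Read a pattern set written by \code{\link{writePatternSet}}
#' @param prefix path prefix used when writing.
#' @return a \linkS4class{PatternSet}.
#' @export
readPatternSet <- function(prefix) {
  md <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  if (!identical(md$schema, "spiOrient-patternset-1"))
    stop("not a spiOrient pattern set")
  q <- cbind(md$qvec$qx, md$qvec$qy, md$qvec$qz)
  pm <- new("PixelMap", q = q, qmag = sqrt(rowSums(q^2)),
            weight = rep(1, nrow(q)), nFast = as.integer(md$nFast),
            nSlow = as.integer(md$nSlow), wavelength = md$wavelength)
  tk <- utils::read.table(paste0(prefix, "_counts.tsv"), header = TRUE)
  K <- Matrix::sparseMatrix(i = tk$pixel, j = tk$pattern, x = tk$count,
                            dims = c(md$nPixels, md$nPatterns))
  ori <- as.matrix(utils::read.table(paste0(prefix, "_orientations.tsv"),
                                     header = TRUE))
  ps <- patternSet(K, ori, pm, meanPhotons = md$meanPhotons %||% NA_real_,
                   background = md$background %||% 0,
                   seed = md$seed %||% NA_integer_,
                   role = md$role %||% "pattern")
  ps
}

#' Write a rotation set as TSV
#' @param rs a \linkS4class{RotationSet}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeRotationSet <- function(rs, path) {
  df <- data.frame(qw = rs@quaternions[, 1], qx = rs@quaternions[, 2],
                   qy = rs@quaternions[, 3], qz = rs@quaternions[, 4],
                   weight = rs@weights)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spiOrient-rotationset level=%d", rs@level), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an experiment plan from a YAML config
#'
#' Recognized top-level keys: \code{water_thickness}, \code{damage},
#' \code{patterns_per_condition}, \code{sentinels_per_condition},
#' \code{emc_repeats}, \code{mean_photons}, \code{background},
#' \code{seed}, \code{scale}, \code{od_source}, a \code{particle} block,
#' an \code{emc} block (fields of \code{\link{emcConfig}} in snake_case)
#' and a \code{geometry} block (\code{n_fast}, \code{n_slow},
#' \code{pixel_size_um}, \code{distance_mm}, \code{photon_energy_keV}).
#'
#' @param path YAML file path.
#' @return an \linkS4class{ExperimentPlan}.
#' @export
readExperimentPlan <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  take <- function(ykey, akey, f = identity) {
    if (!is.null(y[[ykey]])) args[[akey]] <<- f(y[[ykey]])
  }
  take("water_thickness", "waterThickness", as.numeric)
  take("damage", "damage", as.logical)
  take("patterns_per_condition", "patternsPerCondition", as.integer)
  take("sentinels_per_condition", "sentinelsPerCondition", as.integer)
  take("emc_repeats", "emcRepeats", as.integer)
  take("mean_photons", "meanPhotons", as.numeric)
  take("background", "background", as.numeric)
  take("seed", "seed", as.integer)
  take("scale", "scale", as.character)
  take("od_source", "odSource", as.character)
  if (!is.null(y[["particle"]])) args$particle <- y[["particle"]]
  if (!is.null(y[["geometry"]])) {
    g <- y[["geometry"]]
    args$geometry <- detectorGeometry(
      nFast = g[["n_fast"]] %||% 81L, nSlow = g[["n_slow"]] %||% 81L,
      pixelSize = g[["pixel_size_um"]] %||% 1200,
      distance = g[["distance_mm"]] %||% 130,
      photonEnergy = g[["photon_energy_keV"]] %||% 4.96)
  }
  if (!is.null(y[["emc"]])) {
    e <- y[["emc"]]
    args$emc <- emcConfig(
      betaStart = e[["beta_start"]] %||% 0.01,
      betaFactor = e[["beta_factor"]] %||% 1.5,
      betaPeriod = e[["beta_period"]] %||% 10L,
      numDivStart = e[["num_div_start"]] %||% 5L,
      numDivCap = e[["num_div_cap"]] %||% 16L,
      mainIterations = e[["main_iterations"]] %||% 120L,
      finalIterations = e[["final_iterations"]] %||% 10L,
      volumeEdge = e[["volume_edge"]] %||% NA_integer_,
      initSeed = e[["init_seed"]] %||% 1L)
  }
  if (!is.null(y[["od"]])) {
    o <- y[["od"]]
    args$od <- odConfig(
      level = o[["level"]] %||% 4L,
      pointGroup = makeGroup(o[["point_group"]] %||% "C1"),
      epsilon = o[["epsilon"]] %||% 1e-6,
      maxSupport = o[["max_support"]] %||% 256L)
  }
  do.call(experimentPlan, args)
}

#' Export a pixel map to TSV
#' @param pixmap a \linkS4class{PixelMap}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writePixelMap <- function(pixmap, path) {
  df <- data.frame(qx = pixmap@q[, 1], qy = pixmap@q[, 2], qz = pixmap@q[, 3],
                   qmag = pixmap@qmag, weight = pixmap@weight)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
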