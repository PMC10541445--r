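#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats rpois rnorm runif rgamma sd optimize
#' @useDynLib spiOrient, .registration = TRUE
NULL

#' Detector and beam geometry for an Ewald-sphere pixel map
#'
#' Flat square detector centred on the beam axis.  The default values
#' describe the central region of a megapixel detector at a hard X-ray
#' free-electron-laser imaging endstation: an 81 x 81 pixel array with
#' 1200 micrometre pixels, 130 mm from the interaction point, at a photon
#' energy of 4.96 keV.  For an odd pixel count the beam centre defaults to
#' the exact central pixel.
#'
#' @slot nFast,nSlow integer pixel counts along the two detector axes.
#' @slot pixelSize pixel pitch in micrometres.
#' @slot distance sample-to-detector distance in millimetres.
#' @slot photonEnergy photon energy in keV.
#' @slot center fractional pixel coordinates (0-based) of the beam axis.
#' @exportClass DetectorGeometry
setClass("DetectorGeometry",
  representation(nFast = "integer", nSlow = "integer", pixelSize = "numeric",
                 distance = "numeric", photonEnergy = "numeric",
                 center = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@nFast < 1L || object@nSlow < 1L)
      msg <- c(msg, "pixel counts must be positive")
    if (object@pixelSize <= 0) msg <- c(msg, "pixel size must be positive")
    if (object@distance <= 0) msg <- c(msg, "detector distance must be positive")
    if (object@photonEnergy <= 0) msg <- c(msg, "photon energy must be positive")
    if (length(object@center) != 2L) msg <- c(msg, "center must have length 2")
    if (is.null(msg)) TRUE else msg
  })

#' Pixel-to-reciprocal-space map on the Ewald sphere
#'
#' Per-pixel scattering vectors \eqn{q} (\eqn{\lambda^{-1}}-free convention
#' \eqn{q = 2\sin\theta/\lambda}, units \eqn{\mathrm{\AA}^{-1}}), their
#' magnitudes, and a per-pixel integration weight (flat 1 by default;
#' solid-angle or polarization corrections can be supplied through it).
#'
#' @slot q numeric matrix (npixel x 3) of scattering vectors.
#' @slot qmag numeric vector of |q| per pixel.
#' @slot weight numeric vector of integration weights.
#' @slot nFast,nSlow detector dimensions the map was built from.
#' @slot wavelength X-ray wavelength in Angstrom.
#' @exportClass PixelMap
setClass("PixelMap",
  representation(q = "matrix", qmag = "numeric", weight = "numeric",
                 nFast = "integer", nSlow = "integer", wavelength = "numeric"))

#' X-ray beam parameters
#'
#' @slot photonsPerPulse photon count per pulse.
#' @slot photonEnergy photon energy in keV.
#' @slot focusFWHM focal spot full width at half maximum, (x, y) in nm.
#' @slot pulseFDHM pulse full duration at half maximum in fs.
#' @exportClass BeamParameters
setClass("BeamParameters",
  representation(photonsPerPulse = "numeric", photonEnergy = "numeric",
                 focusFWHM = "numeric", pulseFDHM = "numeric"),
  validity = function(object) {
    if (object@photonsPerPulse < 0) return("photon count must be >= 0")
    if (object@photonEnergy <= 0) return("photon energy must be positive")
    if (length(object@focusFWHM) != 2L || any(object@focusFWHM <= 0))
      return("focusFWHM must be two positive lengths (nm)")
    if (object@pulseFDHM <= 0) return("pulse FDHM must be positive")
    TRUE
  })

#' Weighted quadrature sampling of SO(3)
#'
#' Rotation samples obtained by subdividing the 600-cell at refinement
#' level \code{level} (the \code{num_div} parameter of the EMC literature),
#' projecting to the unit 3-sphere and identifying antipodal quaternions.
#' The sample count is \eqn{10(5n^3+n)} at level \eqn{n}; each sample
#' carries a quadrature weight proportional to the summed projected volume
#' of its incident sub-simplices, normalized to sum 1.
#'
#' @slot level positive integer refinement level.
#' @slot quaternions numeric matrix (n x 4), unit rows, w >= 0.
#' @slot weights positive weights summing to 1.
#' @exportClass RotationSet
setClass("RotationSet",
  representation(level = "integer", quaternions = "matrix", weights = "numeric"),
  validity = function(object) {
    n <- nrow(object@quaternions)
    if (length(object@weights) != n) return("weights length mismatch")
    if (any(object@weights <= 0)) return("weights must be strictly positive")
    if (abs(sum(object@weights) - 1) > 1e-10) return("weights must sum to 1")
    nrm <- sqrt(rowSums(object@quaternions^2))
    if (any(abs(nrm - 1) > 1e-9)) return("quaternions must be unit norm")
    TRUE
  })

#' Finite rotation symmetry group
#'
#' @slot name group label (\code{"C1"}, \code{"C2"}, \code{"friedel_z"}).
#' @slot elements numeric matrix (n x 4) of unit quaternions; contains the
#'   identity and is closed under composition and inverse.
#' @exportClass SymmetryGroup
setClass("SymmetryGroup",
  representation(name = "character", elements = "matrix"),
  validity = function(object) {
    if (nrow(object@elements) < 1L) return("group must be non-empty")
    if (ncol(object@elements) != 4L) return("elements must be quaternions")
    TRUE
  })

#' Atomic structure (toy particle, PDB model, or hydrated assembly)
#'
#' Positions in Angstrom, centred on the centroid by the constructors.
#' \code{occupancy} is a per-atom effective-electron scale (1 = neutral
#' atom); the damage stand-in lowers it to emulate ionization.  Water
#' molecules added by \code{\link{addWaterShell}} appear as single
#' effective scatterers with species label \code{"HOH"}.
#'
#' @slot elements character vector of species symbols.
#' @slot positions numeric matrix (n x 3), Angstrom.
#' @slot occupancy numeric per-atom scale factors.
#' @exportClass AtomicStructure
setClass("AtomicStructure",
  representation(elements = "character", positions = "matrix",
                 occupancy = "numeric"),
  validity = function(object) {
    n <- length(object@elements)
    if (nrow(object@positions) != n || ncol(object@positions) != 3L)
      return("positions must be an n x 3 matrix")
    if (length(object@occupancy) != n) return("occupancy length mismatch")
    if (!all(is.finite(object@positions))) return("non-finite coordinates")
    bad <- setdiff(unique(object@elements), supportedElements())
    if (length(bad))
      return(paste("unsupported elements:", paste(bad, collapse = ", ")))
    TRUE
  })

#' Water-shell construction parameters
#'
#' @slot thickness shell thickness T_w in Angstrom (0 adds nothing).
#' @slot numberDensity water molecules per cubic Angstrom (bulk ~ 0.0334).
#' @slot contactDistance closest approach to a solute atom, Angstrom.
#' @slot minSeparation minimum water-water distance, Angstrom.
#' @slot seed integer seed for the dart-throwing placement.
#' @exportClass WaterShellSpec
setClass("WaterShellSpec",
  representation(thickness = "numeric", numberDensity = "numeric",
                 contactDistance = "numeric", minSeparation = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@thickness < 0) return("thickness must be >= 0")
    if (object@numberDensity <= 0) return("number density must be positive")
    if (object@contactDistance <= 0 || object@minSeparation <= 0)
      return("distances must be positive")
    TRUE
  })

#' Temporal pulse profile binned at fixed intervals
#'
#' @slot binTimes bin start times in fs.
#' @slot binFractions fraction of total pulse energy per bin (sums to 1).
#' @slot binWidth bin width in fs (2.6 by default).
#' @exportClass PulseProfile
setClass("PulseProfile",
  representation(binTimes = "numeric", binFractions = "numeric",
                 binWidth = "numeric"),
  validity = function(object) {
    if (length(object@binTimes) != length(object@binFractions))
      return("bin vectors must have equal length")
    if (any(object@binFractions < 0)) return("fractions must be >= 0")
    if (abs(sum(object@binFractions) - 1) > 1e-9)
      return("fractions must sum to 1")
    TRUE
  })

#' Parametric expansion/ionization damage trajectory
#'
#' A phenomenological stand-in for time-resolved radiation damage: per
#' pulse bin, atoms are displaced radially from the centroid by a factor
#' \eqn{1 + e\,D(t)} and the effective electron count is scaled by
#' \eqn{\max(0, 1 - i\,D(t))}, where \eqn{D(t)} is the cumulative pulse
#' fraction deposited before the bin.  This is not a physical ionization
#' model; it reproduces the qualitative signatures (speckle contraction,
#' late-pulse blurring) of damage-driven sample expansion.
#'
#' @slot snapshots list of \linkS4class{AtomicStructure}, one per bin.
#' @slot fractions pulse-energy fraction per bin.
#' @slot doses cumulative dose D(t) at each bin start.
#' @slot expansionRate,ionizationRate the two stand-in parameters.
#' @exportClass DamageTrajectory
setClass("DamageTrajectory",
  representation(snapshots = "list", fractions = "numeric", doses = "numeric",
                 expansionRate = "numeric", ionizationRate = "numeric"))

#' 3D reciprocal-space intensity volume
#'
#' Cubic grid with odd edge length; the central voxel is q = 0 and the
#' voxel pitch is \code{dq} Angstrom^-1.  Used both for ground-truth
#' (ideal) intensities and for EMC reconstructions.
#'
#' @slot values numeric array (edge^3), non-negative.
#' @slot dq voxel size in Angstrom^-1.
#' @slot provenance free-form list (training pattern ids, condition tags).
#' @exportClass IntensityVolume
setClass("IntensityVolume",
  representation(values = "array", dq = "numeric", provenance = "list"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L || length(unique(d)) != 1L)
      return("values must be a cubic array")
    if (d[1] %% 2L == 0L) return("edge must be odd")
    if (object@dq <= 0) return("dq must be positive")
    if (any(object@values < 0)) return("intensities must be >= 0")
    TRUE
  })

#' Photon-sparse diffraction pattern collection
#'
#' Extends \linkS4class{SummarizedExperiment}: the \code{"counts"} assay
#' is a sparse integer matrix (detector pixels x patterns), \code{colData}
#' stores the true orientation quaternion and provenance tags per pattern,
#' and \code{metadata} stores the shared \linkS4class{DetectorGeometry},
#' \linkS4class{PixelMap} and generation parameters.
#'
#' @exportClass PatternSet
setClass("PatternSet", contains = "SummarizedExperiment",
  validity = function(object) {
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
      return("missing 'counts' assay")
    if (is.null(S4Vectors::metadata(object)$pixmap))
      return("missing pixel map in metadata")
    TRUE
  })

#' EMC reconstruction configuration
#'
#' Annealing schedule: starting at (\code{betaStart}, \code{numDivStart}),
#' beta is multiplied by \code{betaFactor} and the rotation refinement
#' level increased by \code{numDivStep} every \code{betaPeriod} iterations
#' for \code{mainIterations} iterations (levels capped at
#' \code{numDivCap}, beta capped at 1), followed by
#' \code{finalIterations} iterations at beta = 1 and level
#' \code{finalNumDiv}.
#'
#' @exportClass EMCConfig
setClass("EMCConfig",
  representation(betaStart = "numeric", betaFactor = "numeric",
                 betaPeriod = "integer", numDivStart = "integer",
                 numDivStep = "integer", numDivCap = "integer",
                 mainIterations = "integer", finalIterations = "integer",
                 finalNumDiv = "integer", volumeEdge = "integer",
                 initSeed = "integer", tomoFloor = "numeric"),
  validity = function(object) {
    if (object@betaStart <= 0 || object@betaStart > 1)
      return("betaStart must be in (0, 1]")
    if (object@betaFactor < 1) return("betaFactor must be >= 1")
    if (object@betaPeriod < 1L) return("betaPeriod must be >= 1")
    if (object@numDivStart < 1L || object@numDivCap < object@numDivStart)
      return("invalid num_div bounds")
    if (object@mainIterations < 0L || object@finalIterations < 0L)
      return("iteration counts must be >= 0")
    TRUE
  })

#' EMC reconstruction state
#'
#' @slot volume final \linkS4class{IntensityVolume}.
#' @slot trace per-iteration data.frame (iteration, beta, numDiv,
#'   meanLogLik, seconds).
#' @slot bestOrientation per-pattern most probable orientation (n x 4).
#' @slot orientationEntropy per-pattern entropy of the orientation
#'   responsibilities (nats).
#' @exportClass EMCState
setClass("EMCState",
  representation(volume = "IntensityVolume", trace = "data.frame",
                 bestOrientation = "matrix", orientationEntropy = "numeric"))

#' Shell specification for the shell R-factor
#'
#' @slot edges strictly increasing q bin edges, Angstrom^-1.
#' @slot regionBreaks boundaries separating the named low/mid/high-q
#'   regions A, B, C (defaults 0.08 and 0.10 Angstrom^-1).
#' @exportClass ShellSpec
setClass("ShellSpec",
  representation(edges = "numeric", regionBreaks = "numeric"),
  validity = function(object) {
    if (any(diff(object@edges) <= 0)) return("edges must be strictly increasing")
    if (length(object@regionBreaks) != 2L)
      return("regionBreaks must have length 2")
    TRUE
  })

#' Shell R-factor result
#'
#' @slot shells data.frame with columns qlo, qhi, qmid, nvox, R.
#' @slot regionMeans named numeric (A, B, C), voxel-weighted means.
#' @exportClass ShellRFactorResult
setClass("ShellRFactorResult",
  representation(shells = "data.frame", regionMeans = "numeric"))

#' Orientation-disconcurrence configuration
#'
#' @slot level rotation-set refinement level used for the posterior grid.
#' @slot pointGroup particle point group s (quotiented out of SO(3)).
#' @slot friedelGroup Friedel group z (identity + pi about the beam axis).
#' @slot epsilon posterior support truncation: smallest set holding
#'   mass >= 1 - epsilon is kept.
#' @slot maxSupport hard cap on support size per sentinel (renormalized).
#' @slot nCandidates number of best coarse candidates refined with the
#'   full double sum.
#' @slot refineSteps local refinement iterations around the best candidate.
#' @exportClass ODConfig
setClass("ODConfig",
  representation(level = "integer", pointGroup = "SymmetryGroup",
                 friedelGroup = "SymmetryGroup", epsilon = "numeric",
                 maxSupport = "integer", nCandidates = "integer",
                 refineSteps = "integer"))

#' Orientation-disconcurrence result
#'
#' @slot deltaTheta the OD value in radians.
#' @slot perSentinelTheta per-sentinel Theta (radians) at the optimum.
#' @slot optimalOrientation the overall orientation absorbed by the
#'   minimization (unit quaternion).
#' @exportClass ODResult
setClass("ODResult",
  representation(deltaTheta = "numeric", perSentinelTheta = "numeric",
                 optimalOrientation = "numeric"))

#' Experiment plan: condition scan over water thickness and damage
#'
#' @exportClass ExperimentPlan
setClass("ExperimentPlan",
  representation(waterThickness = "numeric", damage = "logical",
                 patternsPerCondition = "integer", sentinelsPerCondition = "integer",
                 emcRepeats = "integer", meanPhotons = "numeric",
                 background = "numeric",
                 seed = "integer", scale = "character", particle = "list",
                 emc = "EMCConfig", od = "ODConfig", geometry = "DetectorGeometry",
                 odSource = "character"),
  validity = function(object) {
    if (object@emcRepeats < 1L) return("emcRepeats must be >= 1")
    if (any(object@waterThickness < 0)) return("water thickness must be >= 0")
    TRUE
  })

#' Aggregated experiment report
#'
#' @slot conditions data.frame, one row per condition, with mean and sd of
#'   the self-OD over EMC repeats and region means of the shell R-factor.
#' @slot shellR list of per-condition shell tables (mean and sd over repeats).
#' @slot slices list of per-condition central slices of the reconstructed
#'   volume (first repeat) and the ground truth, for figures.
#' @slot provenance config echo, seeds, package version.
#' @exportClass SPIReport
setClass("SPIReport",
  representation(conditions = "data.frame", shellR = "list", slices = "list",
                 provenance = "list"))
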