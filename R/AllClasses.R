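#' @import methods
NULL

.checkPositive <- function(x, what) {
  if (length(x) == 0 || any(!is.finite(x)) || any(x <= 0))
    sprintf("'%s' must be finite and > 0", what)
  else NULL
}

#' Spinal-cord geometry
#'
#' Dimensions of the simulated spinal cord and its coordinate frame. The
#' dorsoventral (DV) axis runs ventral (0) to dorsal (1), the mediolateral
#' (ML) axis left (0) to right (1), and the anterior-posterior (AP) axis is
#' measured in micrometres. The central canal is placed at a fixed fraction
#' of the DV and ML extents and is the landmark for all profile lines.
#'
#' @slot dvHeight DV height of the cord, micrometres.
#' @slot mlWidth ML width of the cord, micrometres.
#' @slot apLength AP length of the simulated segment, micrometres; must
#'   cover at least five somites.
#' @slot canalDvFrac,canalMlFrac canal position as fractions of the DV / ML
#'   extents (0 = ventral / left edge).
#' @slot somiteLength AP length of one somite, micrometres.
#' @slot cellDiameter nominal cell diameter, micrometres.
#' @name SpinalCordGeometry-class
#' @aliases SpinalCordGeometry-class
#' @exportClass SpinalCordGeometry
setClass("SpinalCordGeometry",
  representation(
    dvHeight = "numeric", mlWidth = "numeric", apLength = "numeric",
    canalDvFrac = "numeric", canalMlFrac = "numeric",
    somiteLength = "numeric", cellDiameter = "numeric"),
  prototype(
    dvHeight = 50, mlWidth = 20, apLength = 250,
    canalDvFrac = 0.3, canalMlFrac = 0.5,
    somiteLength = 50, cellDiameter = 5))

setValidity("SpinalCordGeometry", function(object) {
  msg <- c(
    .checkPositive(object@dvHeight, "dvHeight"),
    .checkPositive(object@mlWidth, "mlWidth"),
    .checkPositive(object@apLength, "apLength"),
    .checkPositive(object@somiteLength, "somiteLength"),
    .checkPositive(object@cellDiameter, "cellDiameter"))
  if (object@canalDvFrac <= 0 || object@canalDvFrac >= 1)
    msg <- c(msg, "'canalDvFrac' must lie strictly inside (0, 1)")
  if (object@canalMlFrac <= 0 || object@canalMlFrac >= 1)
    msg <- c(msg, "'canalMlFrac' must lie strictly inside (0, 1)")
  if (length(msg) == 0 && object@apLength < 5 * object@somiteLength)
    msg <- "'apLength' must cover at least 5 somites"
  if (length(msg) == 0 &&
      object@cellDiameter >= min(object@dvHeight, object@mlWidth))
    msg <- "'cellDiameter' must be smaller than the cord cross-section"
  if (length(msg)) msg else TRUE
})

#' @describeIn SpinalCordGeometry-class constructor with the default
#'   desk-scale zebrafish cord dimensions.
#' @param dvHeight,mlWidth,apLength,canalDvFrac,canalMlFrac,somiteLength,cellDiameter
#'   see slots.
#' @return a \code{SpinalCordGeometry} object.
#' @examples
#' geom <- SpinalCordGeometry()
#' somiteCount(geom)
#' @export
SpinalCordGeometry <- function(dvHeight = 50, mlWidth = 20, apLength = 250,
                               canalDvFrac = 0.3, canalMlFrac = 0.5,
                               somiteLength = 50, cellDiameter = 5) {
  new("SpinalCordGeometry", dvHeight = dvHeight, mlWidth = mlWidth,
      apLength = apLength, canalDvFrac = canalDvFrac,
      canalMlFrac = canalMlFrac, somiteLength = somiteLength,
      cellDiameter = cellDiameter)
}

#' @describeIn SpinalCordGeometry-class number of complete somites spanned
#'   along AP.
#' @param geometry a \code{SpinalCordGeometry}.
#' @export
somiteCount <- function(geometry) {
  as.integer(floor(geometry@apLength / geometry@somiteLength + 1e-9))
}

setMethod("show", "SpinalCordGeometry", function(object) {
  cat("SpinalCordGeometry:",
      sprintf("DV %g um x ML %g um x AP %g um (%d somites)",
              object@dvHeight, object@mlWidth, object@apLength,
              somiteCount(object)), "\n")
  cat(sprintf("  canal at DV %.2f / ML %.2f; cell diameter %g um\n",
              object@canalDvFrac, object@canalMlFrac, object@cellDiameter))
})

#' Three-phase signalling schedule
#'
#' The windows (in hours post-fertilization) of the three phases of
#' spinal-cord signalling dynamics: activation, consolidation, and
#' termination. Windows must be contiguous and ordered.
#'
#' @slot activation,consolidation,termination numeric length-2
#'   \code{[start, end)} windows in hpf.
#' @name PhaseSchedule-class
#' @aliases PhaseSchedule-class
#' @exportClass PhaseSchedule
setClass("PhaseSchedule",
  representation(activation = "numeric", consolidation = "numeric",
                 termination = "numeric"),
  prototype(activation = c(24, 42), consolidation = c(42, 66),
            termination = c(66, 78)))

setValidity("PhaseSchedule", function(object) {
  w <- rbind(object@activation, object@consolidation, object@termination)
  if (ncol(w) != 2) return("each window must be a [start, end) pair")
  if (any(w[, 1] >= w[, 2])) return("each window must have start < end")
  if (object@activation[2] != object@consolidation[1] ||
      object@consolidation[2] != object@termination[1])
    return("phase windows must be contiguous and ordered")
  TRUE
})

#' @describeIn PhaseSchedule-class constructor; defaults to the canonical
#'   (24,42), (42,66), (66,78) hpf windows.
#' @param activation,consolidation,termination \code{[start, end)} in hpf.
#' @export
PhaseSchedule <- function(activation = c(24, 42), consolidation = c(42, 66),
                          termination = c(66, 78)) {
  new("PhaseSchedule", activation = activation,
      consolidation = consolidation, termination = termination)
}

setMethod("show", "PhaseSchedule", function(object) {
  cat(sprintf(
    "PhaseSchedule: activation [%g, %g), consolidation [%g, %g), termination [%g, %g) hpf\n",
    object@activation[1], object@activation[2],
    object@consolidation[1], object@consolidation[2],
    object@termination[1], object@termination[2]))
})

#' Experimental perturbation
#'
#' One condition from the perturbation catalogue: a small-molecule drug
#' (cyclopamine blocks Smoothened; LY-411575 blocks gamma-secretase and
#' hence Notch), an optional heat-shock-induced transgene (NICD, rSmoM2 or
#' EGFP-Gli1), and the genotype (wildtype, iguana, or mindbomb).
#'
#' @slot drug \code{"none"}, \code{"cyclopamine"} or \code{"LY411575"}.
#' @slot drugStart treatment start, hpf.
#' @slot transgene \code{"none"}, \code{"NICD"}, \code{"rSmoM2"} or
#'   \code{"EGFP_Gli1"}.
#' @slot heatshockTime heat-shock time in hpf (length 0 when no transgene).
#' @slot genotype \code{"wildtype"}, \code{"iguana"} or \code{"mindbomb"}.
#' @name PerturbationSpec-class
#' @aliases PerturbationSpec-class
#' @exportClass PerturbationSpec
setClass("PerturbationSpec",
  representation(drug = "character", drugStart = "numeric",
                 transgene = "character", heatshockTime = "numeric",
                 genotype = "character"),
  prototype(drug = "none", drugStart = 0, transgene = "none",
            heatshockTime = numeric(0), genotype = "wildtype"))

.DRUGS <- c("none", "cyclopamine", "LY411575")
.TRANSGENES <- c("none", "NICD", "rSmoM2", "EGFP_Gli1")
.GENOTYPES <- c("wildtype", "iguana", "mindbomb")

setValidity("PerturbationSpec", function(object) {
  msg <- NULL
  if (!object@drug %in% .DRUGS)
    msg <- c(msg, sprintf("unknown drug '%s'", object@drug))
  if (!object@transgene %in% .TRANSGENES)
    msg <- c(msg, sprintf("unknown transgene '%s'", object@transgene))
  if (!object@genotype %in% .GENOTYPES)
    msg <- c(msg, sprintf("unknown genotype '%s'", object@genotype))
  if (length(object@drugStart) != 1 || !is.finite(object@drugStart) ||
      object@drugStart < 0)
    msg <- c(msg, "'drugStart' must be a single hpf value >= 0")
  hsPresent <- length(object@heatshockTime) == 1
  if (object@transgene != "none" && !hsPresent)
    msg <- c(msg, "'heatshockTime' required when a transgene is present")
  if (object@transgene == "none" && hsPresent)
    msg <- c(msg, "'heatshockTime' only meaningful with a transgene")
  if (length(msg)) msg else TRUE
})

#' @describeIn PerturbationSpec-class constructor; the default is the
#'   untreated wild type (the DMSO control).
#' @param drug,drugStart,transgene,heatshockTime,genotype see slots.
#' @export
PerturbationSpec <- function(drug = "none", drugStart = 0,
                             transgene = "none", heatshockTime = numeric(0),
                             genotype = "wildtype") {
  new("PerturbationSpec", drug = drug, drugStart = drugStart,
      transgene = transgene, heatshockTime = heatshockTime,
      genotype = genotype)
}

setMethod("show", "PerturbationSpec", function(object) {
  hs <- if (length(object@heatshockTime))
    sprintf(" (heat shock %g hpf)", object@heatshockTime) else ""
  cat(sprintf("PerturbationSpec: drug %s (from %g hpf), transgene %s%s, genotype %s\n",
              object@drug, object@drugStart, object@transgene, hs,
              object@genotype))
})

#' Kaede reporter kinetic parameters
#'
#' First-order synthesis/decay model of the green and red Kaede pools:
#' \eqn{dG/dt = \alpha a(t) - \delta G}, \eqn{dR/dt = -\delta R}, with an
#' instantaneous photoconversion moving a fraction \eqn{\eta} of the green
#' pool into the red pool at the conversion time.
#'
#' @slot synthesisRate alpha, a.u. per hour per unit pathway activity.
#' @slot decayRate delta, per hour; the default corresponds to a 24 h
#'   protein half-life so converted red Kaede perdures over a 6 h window.
#' @slot maturationLag hours between synthesis and green fluorescence.
#' @slot conversionEfficiency eta, fraction of green converted to red.
#' @slot detectionFloor a.u.; signal at or below this is unobservable.
#' @name ReporterParams-class
#' @aliases ReporterParams-class
#' @exportClass ReporterParams
setClass("ReporterParams",
  representation(synthesisRate = "numeric", decayRate = "numeric",
                 maturationLag = "numeric",
                 conversionEfficiency = "numeric",
                 detectionFloor = "numeric"),
  prototype(synthesisRate = 10, decayRate = log(2) / 24, maturationLag = 0,
            conversionEfficiency = 1, detectionFloor = 1))

setValidity("ReporterParams", function(object) {
  msg <- NULL
  if (object@synthesisRate <= 0) msg <- c(msg, "'synthesisRate' must be > 0")
  if (object@decayRate < 0) msg <- c(msg, "'decayRate' must be >= 0")
  if (object@maturationLag < 0) msg <- c(msg, "'maturationLag' must be >= 0")
  if (object@conversionEfficiency < 0 || object@conversionEfficiency > 1)
    msg <- c(msg, "'conversionEfficiency' must lie in [0, 1]")
  if (object@detectionFloor < 0) msg <- c(msg, "'detectionFloor' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn ReporterParams-class constructor.
#' @param synthesisRate,decayRate,maturationLag,conversionEfficiency,detectionFloor
#'   see slots.
#' @export
ReporterParams <- function(synthesisRate = 10, decayRate = log(2) / 24,
                           maturationLag = 0, conversionEfficiency = 1,
                           detectionFloor = 1) {
  new("ReporterParams", synthesisRate = synthesisRate, decayRate = decayRate,
      maturationLag = maturationLag,
      conversionEfficiency = conversionEfficiency,
      detectionFloor = detectionFloor)
}

setMethod("show", "ReporterParams", function(object) {
  cat(sprintf(
    "ReporterParams: alpha %g /h, delta %g /h (t1/2 %.1f h), eta %g, lag %g h, floor %g\n",
    object@synthesisRate, object@decayRate,
    if (object@decayRate > 0) log(2) / object@decayRate else Inf,
    object@conversionEfficiency, object@maturationLag,
    object@detectionFloor))
})

#' Photoconversion event
#'
#' An instantaneous UV conversion of the green Kaede pool within an AP
#' window at time \code{t0}; cells outside the window are never converted
#' and serve as the unconverted normalization reference.
#'
#' @slot t0 conversion time, hpf.
#' @slot apWindow \code{[start, end]} AP window, micrometres.
#' @slot efficiency conversion efficiency (fraction).
#' @name ConversionEvent-class
#' @aliases ConversionEvent-class
#' @exportClass ConversionEvent
setClass("ConversionEvent",
  representation(t0 = "numeric", apWindow = "numeric",
                 efficiency = "numeric"),
  prototype(t0 = 24, apWindow = c(50, 200), efficiency = 1))

setValidity("ConversionEvent", function(object) {
  msg <- NULL
  if (length(object@apWindow) != 2 ||
      object@apWindow[1] >= object@apWindow[2])
    msg <- c(msg, "'apWindow' must be [start, end] with start < end")
  if (object@efficiency < 0 || object@efficiency > 1)
    msg <- c(msg, "'efficiency' must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn ConversionEvent-class constructor.
#' @param t0,apWindow,efficiency see slots.
#' @export
ConversionEvent <- function(t0, apWindow, efficiency = 1) {
  new("ConversionEvent", t0 = t0, apWindow = apWindow,
      efficiency = efficiency)
}

setMethod("show", "ConversionEvent", function(object) {
  cat(sprintf("ConversionEvent: t0 %g hpf, AP window [%g, %g] um, efficiency %g\n",
              object@t0, object@apWindow[1], object@apWindow[2],
              object@efficiency))
})

#' Optics model for stack rendering
#'
#' @slot voxelSize micrometres per voxel along (ML, DV, AP).
#' @slot psfSigma Gaussian point-spread sigma, micrometres per axis.
#' @slot backgroundOffset constant camera offset, counts.
#' @name OpticsModel-class
#' @aliases OpticsModel-class
#' @exportClass OpticsModel
setClass("OpticsModel",
  representation(voxelSize = "numeric", psfSigma = "numeric",
                 backgroundOffset = "numeric"),
  prototype(voxelSize = c(1, 1, 1), psfSigma = c(1, 1, 1),
            backgroundOffset = 5))

setValidity("OpticsModel", function(object) {
  msg <- NULL
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    msg <- c(msg, "'voxelSize' must be 3 positive values (ML, DV, AP)")
  if (length(object@psfSigma) != 3 || any(object@psfSigma < 0))
    msg <- c(msg, "'psfSigma' must be 3 values >= 0")
  if (object@backgroundOffset < 0)
    msg <- c(msg, "'backgroundOffset' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn OpticsModel-class constructor.
#' @param voxelSize,psfSigma,backgroundOffset see slots.
#' @export
OpticsModel <- function(voxelSize = c(1, 1, 1), psfSigma = c(1, 1, 1),
                        backgroundOffset = 5) {
  if (length(voxelSize) == 1) voxelSize <- rep(voxelSize, 3)
  if (length(psfSigma) == 1) psfSigma <- rep(psfSigma, 3)
  new("OpticsModel", voxelSize = voxelSize, psfSigma = psfSigma,
      backgroundOffset = backgroundOffset)
}

#' Noise model for stack rendering
#'
#' Poisson shot noise on gain-scaled photon counts followed by additive
#' Gaussian read noise. \code{seed} makes renders reproducible.
#'
#' @slot photonGain counts per a.u. of fluorophore.
#' @slot readNoiseSigma read-noise standard deviation, counts.
#' @slot shotNoise logical; apply Poisson shot noise.
#' @slot seed integer seed; renders are deterministic given the seed.
#' @name NoiseModel-class
#' @aliases NoiseModel-class
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(photonGain = "numeric", readNoiseSigma = "numeric",
                 shotNoise = "logical", seed = "integer"),
  prototype(photonGain = 50, readNoiseSigma = 2, shotNoise = TRUE,
            seed = 1L))

setValidity("NoiseModel", function(object) {
  msg <- NULL
  if (object@photonGain <= 0) msg <- c(msg, "'photonGain' must be > 0")
  if (object@readNoiseSigma < 0)
    msg <- c(msg, "'readNoiseSigma' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn NoiseModel-class constructor; \code{noiseOff()} returns a
#'   noiseless model useful for planted-truth tests.
#' @param photonGain,readNoiseSigma,shotNoise,seed see slots.
#' @export
NoiseModel <- function(photonGain = 50, readNoiseSigma = 2,
                       shotNoise = TRUE, seed = 1L) {
  new("NoiseModel", photonGain = photonGain, readNoiseSigma = readNoiseSigma,
      shotNoise = shotNoise, seed = as.integer(seed))
}

#' @describeIn NoiseModel-class noiseless rendering model (unit gain, no
#'   shot or read noise).
#' @param gain photon gain for the noiseless model.
#' @export
noiseOff <- function(gain = 1) NoiseModel(photonGain = gain,
  readNoiseSigma = 0, shotNoise = FALSE, seed = 0L)

#' Two-channel image stack
#'
#' A lateral-view confocal stack with axes Z = ML (imaging depth),
#' Y = DV (ventral at the low index), X = AP, and two channels (green,
#' red). Stored as a 4D array indexed \code{[Z, Y, X, channel]}.
#'
#' @slot data numeric 4D array \code{[Z, Y, X, C]}, counts.
#' @slot voxelSize micrometres per voxel along (Z=ML, Y=DV, X=AP).
#' @slot convertedApWindow \code{[start, end]} of the photoconverted AP
#'   span, micrometres (length 0 if nothing was converted).
#' @slot channels channel names.
#' @slot meta free-form list (geometry sidecar, timing, condition).
#' @name KaedeStack-class
#' @aliases KaedeStack-class
#' @exportClass KaedeStack
setClass("KaedeStack",
  representation(data = "array", voxelSize = "numeric",
                 convertedApWindow = "numeric", channels = "character",
                 meta = "list"),
  prototype(data = array(0, c(1, 1, 1, 2)), voxelSize = c(1, 1, 1),
            convertedApWindow = numeric(0),
            channels = c("green", "red"), meta = list()))

setValidity("KaedeStack", function(object) {
  msg <- NULL
  d <- dim(object@data)
  if (length(d) != 4)
    msg <- c(msg, "'data' must be a 4D [Z, Y, X, C] array")
  else if (d[4] != length(object@channels))
    msg <- c(msg, "channel count must match length(channels)")
  if (any(object@data < 0)) msg <- c(msg, "intensities must be >= 0")
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    msg <- c(msg, "'voxelSize' must be 3 positive values")
  if (length(object@convertedApWindow) == 2) {
    apExtent <- dim(object@data)[3] * object@voxelSize[3]
    w <- object@convertedApWindow
    if (w[1] >= w[2] || w[1] < 0 || w[2] > apExtent + 1e-9)
      msg <- c(msg, "'convertedApWindow' must lie within the AP extent")
  } else if (length(object@convertedApWindow) != 0)
    msg <- c(msg, "'convertedApWindow' must be empty or [start, end]")
  if (length(msg)) msg else TRUE
})

#' @describeIn KaedeStack-class constructor.
#' @param data,voxelSize,convertedApWindow,channels,meta see slots.
#' @export
KaedeStack <- function(data, voxelSize = c(1, 1, 1),
                       convertedApWindow = numeric(0),
                       channels = c("green", "red"), meta = list()) {
  new("KaedeStack", data = data, voxelSize = voxelSize,
      convertedApWindow = convertedApWindow, channels = channels,
      meta = meta)
}

setMethod("show", "KaedeStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("KaedeStack: Z %d x Y %d x X %d voxels, %d channel(s) [%s]\n",
              d[1], d[2], d[3], d[4], paste(object@channels, collapse = ", ")))
  cat(sprintf("  voxel size (%s) um; converted AP window: %s\n",
              paste(object@voxelSize, collapse = ", "),
              if (length(object@convertedApWindow))
                sprintf("[%g, %g] um", object@convertedApWindow[1],
                        object@convertedApWindow[2]) else "none"))
})

#' @describeIn KaedeStack-class voxel data accessor; optionally one channel.
#' @param stack a \code{KaedeStack}.
#' @param channel channel name or index (optional).
#' @export
stackData <- function(stack, channel = NULL) {
  if (is.null(channel)) return(stack@data)
  if (is.character(channel)) channel <- match(channel, stack@channels)
  if (is.na(channel) || channel < 1 || channel > dim(stack@data)[4])
    stop("unknown channel")
  stack@data[, , , channel, drop = TRUE]
}

#' @describeIn KaedeStack-class voxel size accessor (ML, DV, AP; um/voxel).
#' @export
voxelSize <- function(stack) stack@voxelSize

#' @describeIn KaedeStack-class converted AP window accessor (um).
#' @export
convertedApWindow <- function(stack) stack@convertedApWindow

#' Intensity profile along the DV or ML axis
#'
#' Positions are fractions of the axis extent (0 to 1); values are percent
#' of the unconverted-region green maximum, so profiles from different
#' embryos are directly comparable.
#'
#' @slot axis \code{"DV"} or \code{"ML"}.
#' @slot positions strictly increasing fractions in [0, 1].
#' @slot values intensity, percent of the unconverted green reference.
#' @slot canalFrac canal position as a fraction of the axis extent.
#' @slot nLines number of traces averaged.
#' @slot nSomites number of somite sections averaged.
#' @name IntensityProfile-class
#' @aliases IntensityProfile-class
#' @exportClass IntensityProfile
setClass("IntensityProfile",
  representation(axis = "character", positions = "numeric",
                 values = "numeric", canalFrac = "numeric",
                 nLines = "integer", nSomites = "integer"),
  prototype(axis = "DV", positions = numeric(0), values = numeric(0),
            canalFrac = NA_real_, nLines = 1L, nSomites = 1L))

setValidity("IntensityProfile", function(object) {
  msg <- NULL
  if (!object@axis %in% c("DV", "ML"))
    msg <- c(msg, "'axis' must be \"DV\" or \"ML\"")
  if (length(object@positions) != length(object@values))
    msg <- c(msg, "positions and values must have equal length")
  if (length(object@positions) > 1 && any(diff(object@positions) <= 0))
    msg <- c(msg, "'positions' must be strictly increasing")
  if (length(object@positions) &&
      (min(object@positions) < 0 || max(object@positions) > 1))
    msg <- c(msg, "'positions' must lie in [0, 1]")
  if (any(object@values < 0)) msg <- c(msg, "'values' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn IntensityProfile-class constructor.
#' @param axis,positions,values,canalFrac,nLines,nSomites see slots.
#' @export
IntensityProfile <- function(axis, positions, values, canalFrac = NA_real_,
                             nLines = 1L, nSomites = 1L) {
  new("IntensityProfile", axis = axis, positions = positions,
      values = values, canalFrac = canalFrac, nLines = as.integer(nLines),
      nSomites = as.integer(nSomites))
}

setMethod("show", "IntensityProfile", function(object) {
  cat(sprintf(
    "IntensityProfile (%s): %d positions, peak %.1f%% at %.2f; %d line(s) x %d somite(s)\n",
    object@axis, length(object@positions),
    if (length(object@values)) max(object@values) else NA,
    if (length(object@values))
      object@positions[which.max(object@values)] else NA,
    object@nLines, object@nSomites))
})

#' @describeIn IntensityProfile-class accessors for positions / values.
#' @param profile an \code{IntensityProfile}.
#' @export
profilePositions <- function(profile) profile@positions

#' @describeIn IntensityProfile-class value accessor.
#' @export
profileValues <- function(profile) profile@values

#' Spatiotemporal signalling map
#'
#' Per-conversion-timepoint averaged DV/ML profiles and response-class
#' composition, assembled over a grid of photoconversion times.
#'
#' @slot t0 strictly increasing conversion times, hpf.
#' @slot dvProfiles,mlProfiles lists of \code{IntensityProfile}, one per t0.
#' @slot classFractions matrix [t0 x class] of voxel fractions per
#'   response class (new, continued, past, none).
#' @name SpatiotemporalMap-class
#' @aliases SpatiotemporalMap-class
#' @exportClass SpatiotemporalMap
setClass("SpatiotemporalMap",
  representation(t0 = "numeric", dvProfiles = "list", mlProfiles = "list",
                 classFractions = "matrix"))

setValidity("SpatiotemporalMap", function(object) {
  msg <- NULL
  if (length(object@t0) > 1 && any(diff(object@t0) <= 0))
    msg <- c(msg, "'t0' grid must be strictly increasing")
  if (length(object@dvProfiles) != length(object@t0) ||
      length(object@mlProfiles) != length(object@t0))
    msg <- c(msg, "one DV and one ML profile required per t0")
  if (nrow(object@classFractions) != length(object@t0))
    msg <- c(msg, "'classFractions' must have one row per t0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpatiotemporalMap", function(object) {
  cat(sprintf("SpatiotemporalMap: %d conversion timepoints (%g..%g hpf)\n",
              length(object@t0), min(object@t0), max(object@t0)))
  cat("  class composition (fraction of cord voxels):\n")
  print(round(object@classFractions, 3))
})
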