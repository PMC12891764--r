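#' @import methods
#' @importFrom stats approx cor median pnorm pt quantile rnorm sd var runif
#' @importFrom utils head tail read.csv write.csv
NULL

#' Volume3D: a gridded scalar image with physical voxel spacing
#'
#' Carrier for all morphological inputs (T1-like brain stacks, BFFE-like
#' aqueduct volumes). Axis order is \code{[x, y, z]} and pixel centers sit at
#' \code{(index - 1) * spacing} millimetres, so voxel \code{[1,1,1]} is at the
#' physical origin. Synthetic volumes carry their generating ground truth in
#' \code{groundTruth} (analytic areas, centerline, diameter profile, ...).
#'
#' @slot data three-dimensional numeric array
#' @slot spacingMm numeric length-3 voxel spacing in mm (x, y, z)
#' @slot groundTruth list of generator ground-truth records (may be empty)
#' @export
setClass("Volume3D",
  representation(data = "array", spacingMm = "numeric", groundTruth = "list"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (length(object@spacingMm) != 3L || any(!is.finite(object@spacingMm)) ||
        any(object@spacingMm <= 0))
      msg <- c(msg, "spacingMm must be 3 positive finite numbers")
    if (length(msg)) msg else TRUE
  })

#' CinePCSeries: paired magnitude/velocity frames over one cardiac cycle
#'
#' Holds one cine phase-contrast acquisition: \code{nFrames} magnitude and
#' signed velocity frames spanning one averaged cardiac cycle, with the
#' velocity-encoding limit (VENC) and cycle duration as metadata. Velocities
#' are in cm/s as acquired; positive values follow the stated direction label
#' (caudo-cranial / fourth-to-third ventricle by convention).
#'
#' @slot magnitude numeric array \code{[x, y, t]}, non-negative
#' @slot velocityCms numeric array \code{[x, y, t]}, signed, cm/s
#' @slot vencCms velocity-encoding limit in cm/s
#' @slot cycleMs averaged cardiac cycle duration in ms
#' @slot pixelAreaMm2 in-plane pixel area in mm^2
#' @slot spacingMm in-plane pixel spacing (x, y) in mm
#' @slot positiveDirection free-text label of the positive flow direction
#' @slot groundTruth list of generator ground truth (may be empty)
#' @export
setClass("CinePCSeries",
  representation(magnitude = "array", velocityCms = "array",
    vencCms = "numeric", cycleMs = "numeric", pixelAreaMm2 = "numeric",
    spacingMm = "numeric", positiveDirection = "character",
    groundTruth = "list"),
  validity = function(object) {
    msg <- character()
    dm <- dim(object@magnitude); dv <- dim(object@velocityCms)
    if (length(dm) != 3L || length(dv) != 3L || !all(dm == dv))
      msg <- c(msg, "magnitude and velocityCms must be 3D arrays of equal dim")
    if (length(dm) == 3L && dm[3] < 2L)
      msg <- c(msg, "need at least 2 frames")
    if (any(object@magnitude < 0))
      msg <- c(msg, "magnitude must be non-negative")
    if (object@vencCms <= 0) msg <- c(msg, "vencCms must be positive")
    if (object@cycleMs <= 0) msg <- c(msg, "cycleMs must be positive")
    if (length(msg)) msg else TRUE
  })

#' FlowCurve: a sampled flow-rate waveform over one cardiac cycle
#'
#' @slot timesMs sample times in ms, strictly increasing, within one cycle
#' @slot flowMm3s flow rate per frame in mm^3/s (ROI area times mean velocity)
#' @slot roiAreaMm2 fixed ROI area in mm^2
#' @slot cycleMs cardiac cycle duration in ms
#' @export
setClass("FlowCurve",
  representation(timesMs = "numeric", flowMm3s = "numeric",
    roiAreaMm2 = "numeric", cycleMs = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@timesMs) != length(object@flowMm3s))
      msg <- c(msg, "timesMs and flowMm3s must have equal length")
    if (any(diff(object@timesMs) <= 0))
      msg <- c(msg, "timesMs must be strictly increasing")
    if (length(object@timesMs) &&
        object@timesMs[length(object@timesMs)] >= object@cycleMs + 1e-9)
      msg <- c(msg, "timesMs must lie within one cycle")
    if (length(msg)) msg else TRUE
  })

#' StrokeVolume: directional integrals of a flow curve
#'
#' \code{sv} is the mean of the positive- and negative-direction stroke
#' volumes, the CSF volume displaced through the plane per cardiac cycle.
#'
#' @slot svPosMm3 integral of positive flow, mm^3
#' @slot svNegMm3 magnitude of the integral of negative flow, mm^3
#' @slot svMm3 mean of the two, mm^3
#' @export
setClass("StrokeVolume",
  representation(svPosMm3 = "numeric", svNegMm3 = "numeric", svMm3 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@svPosMm3 < 0 || object@svNegMm3 < 0)
      msg <- c(msg, "directional stroke volumes must be non-negative")
    if (abs(object@svMm3 - (object@svPosMm3 + object@svNegMm3) / 2) >
        1e-12 * max(1, object@svMm3))
      msg <- c(msg, "svMm3 must equal (svPosMm3 + svNegMm3)/2")
    if (length(msg)) msg else TRUE
  })

#' MorphometryResult: per-slice ventricular morphometry
#'
#' @slot areaVentMm2 segmented ventricular area (plexus excluded), mm^2
#' @slot areaBrainMm2 segmented brain-tissue area (plexus excluded), mm^2
#' @slot ratioArea areaVent / areaBrain as a fraction
#' @slot sliceIndex selected slice (1-based)
#' @slot thresholdUsed intensity threshold applied
#' @export
setClass("MorphometryResult",
  representation(areaVentMm2 = "numeric", areaBrainMm2 = "numeric",
    ratioArea = "numeric", sliceIndex = "integer", thresholdUsed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@areaVentMm2 < 0 || object@areaBrainMm2 < 0)
      msg <- c(msg, "areas must be non-negative")
    if (object@areaBrainMm2 > 0) {
      if (abs(object@ratioArea -
              object@areaVentMm2 / object@areaBrainMm2) > 1e-12)
        msg <- c(msg, "ratioArea must equal areaVentMm2/areaBrainMm2")
      if (object@ratioArea < 0 || object@ratioArea >= 1)
        msg <- c(msg, "ratioArea must be in [0, 1)")
    }
    if (length(msg)) msg else TRUE
  })

#' AqueductProfile: microchannel decomposition of the aqueduct
#'
#' Ordered list of microchannel segments (length, local diameter, segmental
#' Poiseuille resistance), the cumulative-resistance curve, and the effective
#' endpoint where cumulative resistance first reaches the endpoint fraction
#' (95% by default) of the total.
#'
#' @slot microchannels data.frame with columns \code{i, lengthMm, diameterMm,
#'   resistance, cumResistance} (resistance in mPa s/mm^3; cumResistance may
#'   be NA before \code{poiseuilleResistance} is applied)
#' @slot centerlineMm matrix (n x 2) of resampled centerline points in mm
#' @slot userLengthMm arc length between the user-supplied start/end points
#' @slot endpointIndex first segment index reaching the cumulative cutoff
#'   (NA before \code{effectiveEndpoint})
#' @slot effectiveLengthMm arc length from start to the endpoint segment's end
#' @slot totalResistance sum of all segmental resistances, mPa s/mm^3
#' @slot effectiveResistance cumulative resistance at the endpoint, mPa s/mm^3
#' @slot dMeanMm mean diameter over the effective length
#' @slot dMinMm minimum diameter over the effective length
#' @slot params the \code{resistanceParams} list used
#' @export
setClass("AqueductProfile",
  representation(microchannels = "data.frame", centerlineMm = "matrix",
    userLengthMm = "numeric", endpointIndex = "integer",
    effectiveLengthMm = "numeric", totalResistance = "numeric",
    effectiveResistance = "numeric", dMeanMm = "numeric", dMinMm = "numeric",
    params = "list"),
  validity = function(object) {
    msg <- character()
    mc <- object@microchannels
    need <- c("i", "lengthMm", "diameterMm", "resistance", "cumResistance")
    if (!all(need %in% names(mc)))
      msg <- c(msg, paste("microchannels needs columns:",
                          paste(need, collapse = ", ")))
    else {
      if (any(mc$lengthMm <= 0)) msg <- c(msg, "segment lengths must be > 0")
      if (any(mc$diameterMm <= 0)) msg <- c(msg, "diameters must be > 0")
      cr <- mc$cumResistance
      if (!anyNA(cr) && any(diff(cr) < -1e-9))
        msg <- c(msg, "cumResistance must be nondecreasing")
    }
    if (length(msg)) msg else TRUE
  })
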