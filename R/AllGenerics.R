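#' Accessors for aqueflow data classes
#'
#' Small accessor generics so downstream code never reaches into slots:
#' \code{volData} returns the raw array of a \code{Volume3D},
#' \code{voxelSpacing} the voxel spacing in mm, \code{groundTruth} the
#' generator ground-truth record, \code{nFrames} the number of cine frames,
#' and \code{microchannels} the per-segment table of an
#' \code{AqueductProfile}.
#'
#' @param object an aqueflow S4 object
#' @return the corresponding slot value
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(object) standardGeneric("volData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("microchannels", function(object) standardGeneric("microchannels"))

#' @rdname accessors
#' @export
setMethod("volData", "Volume3D", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "Volume3D", function(object) object@spacingMm)
#' @rdname accessors
#' @export
setMethod("groundTruth", "Volume3D", function(object) object@groundTruth)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "CinePCSeries", function(object) object@spacingMm)
#' @rdname accessors
#' @export
setMethod("groundTruth", "CinePCSeries", function(object) object@groundTruth)
#' @rdname accessors
#' @export
setMethod("nFrames", "CinePCSeries",
          function(object) dim(object@velocityCms)[3])
#' @rdname accessors
#' @export
setMethod("microchannels", "AqueductProfile",
          function(object) object@microchannels)

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@data)
  cat("Volume3D:", paste(d, collapse = " x "), "voxels,",
      paste(signif(object@spacingMm, 3), collapse = " x "), "mm spacing\n")
  cat("  intensity range:", paste(signif(range(object@data), 4),
                                  collapse = " .. "), "\n")
  if (length(object@groundTruth))
    cat("  ground truth:", paste(names(object@groundTruth), collapse = ", "),
        "\n")
})

setMethod("show", "CinePCSeries", function(object) {
  d <- dim(object@velocityCms)
  cat("CinePCSeries:", d[1], "x", d[2], "pixels,", d[3], "frames\n")
  cat("  VENC", object@vencCms, "cm/s, cycle", object@cycleMs,
      "ms, pixel area", signif(object@pixelAreaMm2, 4), "mm^2\n")
  cat("  positive direction:", object@positiveDirection, "\n")
})

setMethod("show", "FlowCurve", function(object) {
  cat("FlowCurve:", length(object@flowMm3s), "samples over",
      object@cycleMs, "ms, ROI", signif(object@roiAreaMm2, 4), "mm^2\n")
  cat("  flow range:", paste(signif(range(object@flowMm3s), 4),
                             collapse = " .. "), "mm^3/s\n")
})

setMethod("show", "StrokeVolume", function(object) {
  cat(sprintf("StrokeVolume: SV+ %.3f, SV- %.3f, SV %.3f mm^3\n",
              object@svPosMm3, object@svNegMm3, object@svMm3))
})

setMethod("show", "MorphometryResult", function(object) {
  cat(sprintf(
    "MorphometryResult: slice %d, Area-vent %.2f mm^2, Area-brain %.2f mm^2\n",
    object@sliceIndex, object@areaVentMm2, object@areaBrainMm2))
  cat(sprintf("  Ratio-Area %.3f%% (threshold %.4g)\n",
              100 * object@ratioArea, object@thresholdUsed))
})

setMethod("show", "AqueductProfile", function(object) {
  n <- nrow(object@microchannels)
  cat("AqueductProfile:", n, "microchannels, user length",
      sprintf("%.2f mm", object@userLengthMm), "\n")
  if (!is.na(object@endpointIndex)) {
    cat(sprintf(
      "  effective: %.2f mm (endpoint segment %d), R %.2f mPa s/mm^3\n",
      object@effectiveLengthMm, object@endpointIndex,
      object@effectiveResistance))
    cat(sprintf("  D mean %.3f mm, D min %.3f mm (over effective length)\n",
                object@dMeanMm, object@dMinMm))
  }
})
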