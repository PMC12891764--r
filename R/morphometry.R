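# Ventricular morphometry: interpolate a T1-like slice to a fine grid,
# derive an intensity threshold (max-gradient along a crossing line, or an
# automatic Otsu fallback), binarize inside rough ROIs, and form the
# ventricle-to-brain area ratio (Ratio-Area) on the slice that maximizes it.

#' Threshold from the maximum intensity gradient along a line
#'
#' Samples the intensity profile along a line (or open polyline) at
#' sub-pixel steps and returns the intensity at the point of maximum
#' absolute first difference, i.e. the boundary the line crosses. Ties are
#' broken by the first occurrence along the line.
#'
#' @param img 2D image (see \code{\link{image2d}})
#' @param line n x 2 matrix of 0-based pixel coordinates (n >= 2)
#' @param stepPx sampling step along the line in pixels
#' @return scalar intensity threshold
#' @export
thresholdMaxGradient <- function(img, line, stepPx = 0.25) {
  line <- as.matrix(line)
  stopifnot(nrow(line) >= 2L)
  seg <- sqrt(rowSums(diff(line)^2))
  total <- sum(seg)
  if (total <= 0) stop("degenerate line")
  nS <- max(ceiling(total / stepPx) + 1L, 3L)
  pts <- resamplePolyline(line, nS)
  prof <- sampleBilinear(img, pts)
  d <- abs(diff(prof))
  if (max(d) <= max(.Machine$double.eps * max(abs(prof), 1), 0)) {
    stop("flat intensity profile: no boundary found along the line")
  }
  # a boundary that is linear at the sampling scale gives a plateau of
  # equal gradients: take the middle of the plateau containing the first
  # maximum, so the threshold sits at the edge midpoint; separated equal
  # maxima are still resolved by first occurrence
  kMax <- which.max(d)
  tol <- 1e-9 * diff(range(prof))
  tied <- d >= d[kMax] - tol
  run <- rle(tied)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  w <- which(starts <= kMax & ends >= kMax)
  k <- floor((starts[w] + ends[w]) / 2)
  (prof[k] + prof[k + 1]) / 2
}

#' Binarize an image inside a polygonal ROI
#'
#' Pixels inside the ROI are labeled 0 if below the threshold and 1
#' otherwise; pixels outside the ROI are NA. \code{polarity} names which
#' class is the structure of interest (\code{"dark"} = label 0, as for
#' ventricles on T1; \code{"bright"} = label 1) and only drives the
#' empty-foreground warning.
#'
#' @param img 2D image
#' @param roi polygon (n x 2, 0-based pixel coordinates) or a logical mask
#' @param threshold intensity cutoff; a threshold below (above) the image
#'   range labels everything 1 (0)
#' @param polarity \code{"dark"} or \code{"bright"}
#' @return integer matrix of 0/1 labels with NA outside the ROI
#' @export
binarizeRegion <- function(img, roi, threshold,
                           polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  roiMask <- if (is.matrix(roi) && is.logical(roi)) roi
  else polygonMask(dim(img), roi)
  lab <- matrix(NA_integer_, nrow(img), ncol(img))
  lab[roiMask] <- as.integer(img[roiMask] >= threshold)
  fg <- if (polarity == "dark") 0L else 1L
  if (!any(lab == fg, na.rm = TRUE))
    warning("empty foreground after binarization")
  lab
}

#' Ventricle-to-brain area ratio from labeled masks
#'
#' Area-vent counts label-0 (dark) pixels inside the ventricular ROI with
#' choroid-plexus pixels excluded; Area-brain counts label-1 (bright)
#' pixels inside the brain ROI, also excluding the plexus. Both are scaled
#' by the pixel area; Ratio-Area is their quotient.
#'
#' @param ventLabels,brainLabels 0/1 label matrices with NA outside the
#'   respective ROI (from \code{\link{binarizeRegion}})
#' @param plexusMask logical matrix of plexus pixels (or NULL)
#' @param pixelAreaMm2 area of one pixel in mm^2
#' @param sliceIndex slice the masks came from (stored in the result)
#' @param threshold threshold used (stored in the result)
#' @return a \code{MorphometryResult}
#' @export
measureRatioArea <- function(ventLabels, brainLabels, plexusMask = NULL,
                             pixelAreaMm2, sliceIndex = 1L, threshold = NA) {
  stopifnot(all(dim(ventLabels) == dim(brainLabels)))
  if (is.null(plexusMask)) plexusMask <- matrix(FALSE, nrow(ventLabels),
                                                ncol(ventLabels))
  stopifnot(all(dim(plexusMask) == dim(ventLabels)))
  nVent <- sum(ventLabels == 0L & !plexusMask, na.rm = TRUE)
  nBrain <- sum(brainLabels == 1L & !plexusMask, na.rm = TRUE)
  areaVent <- nVent * pixelAreaMm2
  areaBrain <- nBrain * pixelAreaMm2
  if (areaBrain <= 0) stop("zero brain area: cannot form Ratio-Area")
  new("MorphometryResult", areaVentMm2 = areaVent,
      areaBrainMm2 = areaBrain, ratioArea = areaVent / areaBrain,
      sliceIndex = as.integer(sliceIndex), thresholdUsed = as.numeric(threshold))
}

# Morphometry of a single slice: interpolate, threshold, binarize, measure.
# ROIs are polygons in the *original* pixel grid; they are rescaled to the
# interpolated grid. The plexus is taken as bright pixels inside the
# ventricular ROI (the plexus is the only bright structure there).
measureSliceMorphometry <- function(slice, rois, sliceIndex,
                                    targetSpacingMm = 0.1,
                                    thresholdLine = NULL) {
  sp <- pixelSpacing(slice)
  fine <- interpolateToResolution(slice, targetSpacingMm)
  scaleRoi <- function(poly)
    cbind(poly[, 1] * sp[1] / targetSpacingMm,
          poly[, 2] * sp[2] / targetSpacingMm)
  ventPoly <- scaleRoi(rois$ventricle)
  brainPoly <- scaleRoi(rois$brain)
  thr <- if (!is.null(thresholdLine))
    thresholdMaxGradient(fine, scaleRoi(thresholdLine))
  else otsuThreshold(fine[polygonMask(dim(fine), brainPoly)])
  ventLab <- binarizeRegion(fine, ventPoly, thr, "dark")
  brainLab <- suppressWarnings(binarizeRegion(fine, brainPoly, thr, "bright"))
  # choroid plexus: bright connected components lying wholly inside the
  # (rough) ventricular ROI -- isolated bright islands within the dark
  # ventricles; the brain itself always crosses the ROI border
  ventRoiMask <- !is.na(ventLab)
  lab <- EBImage::bwlabel(fine >= thr)
  insideIds <- setdiff(unique(lab[ventRoiMask]), 0)
  outsideIds <- unique(lab[!ventRoiMask])
  plexusIds <- setdiff(insideIds, outsideIds)
  plexus <- matrix(lab %in% plexusIds, nrow(lab), ncol(lab))
  measureRatioArea(ventLab, brainLab, plexus,
                   pixelAreaMm2 = prod(pixelSpacing(fine)),
                   sliceIndex = sliceIndex, threshold = thr)
}

#' Select the slice with the maximal Ratio-Area
#'
#' Runs the per-slice morphometry (interpolation, thresholding,
#' binarization, area measurement) on every candidate slice and returns the
#' one maximizing Ratio-Area; ties are broken by the lowest slice index.
#'
#' @param volume a \code{Volume3D} (T1-like stack)
#' @param rois list with polygons \code{ventricle} and \code{brain}
#'   (0-based pixel coordinates of the native grid), either shared across
#'   slices or a list of such lists (one per candidate slice)
#' @param slices candidate slice indices (default: all)
#' @param targetSpacingMm interpolation target (default 0.1 mm)
#' @param thresholdLine optional gradient line for thresholding (native
#'   pixel coordinates); if NULL an Otsu threshold inside the brain ROI is
#'   used
#' @return the winning \code{MorphometryResult} (its \code{sliceIndex}
#'   slot identifies the slice)
#' @export
selectMaxRatioSlice <- function(volume, rois, slices = NULL,
                                targetSpacingMm = 0.1,
                                thresholdLine = NULL) {
  stopifnot(is(volume, "Volume3D"))
  dat <- volData(volume)
  sp <- voxelSpacing(volume)
  if (is.null(slices)) slices <- seq_len(dim(dat)[3])
  stopifnot(length(slices) >= 1L)
  best <- NULL
  for (k in slices) {
    r <- if (!is.null(rois$ventricle)) rois else rois[[k]]
    sl <- image2d(dat[, , k], sp[1:2])
    res <- measureSliceMorphometry(sl, r, k, targetSpacingMm, thresholdLine)
    if (is.null(best) || res@ratioArea > best@ratioArea) best <- res
  }
  best
}
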