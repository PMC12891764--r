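# CSF flow quantification from cine phase-contrast series: velocity-based
# ROI segmentation, temporal de-aliasing, static-tissue background phase
# correction, flow-rate curves, directional stroke volumes, and the
# aqueduct-to-cervical stroke-volume ratio with its cardiac-cycle-mismatch
# quality check.

#' Flow-analysis thresholds
#'
#' @param kAmp ROI criterion: peak-to-peak velocity amplitude must exceed
#'   \code{kAmp} times the background (median) amplitude
#' @param cMin minimum correlation of a pixel's waveform with the seed
#'   pixel's waveform
#' @param annulusPx width (pixels) of the dilation ring used to find static
#'   tissue around the ROI
#' @param magFloorFrac static-tissue magnitude floor as a fraction of the
#'   99th-percentile magnitude
#' @param sdCapCms maximum temporal velocity SD for a pixel to count as
#'   static, cm/s
#' @return a list of class \code{flowParams}
#' @export
flowParams <- function(kAmp = 3, cMin = 0.5, annulusPx = 6L,
                       magFloorFrac = 0.2, sdCapCms = 1.0) {
  stopifnot(kAmp > 0, cMin >= -1, cMin <= 1, annulusPx >= 1,
            magFloorFrac >= 0, sdCapCms > 0)
  structure(list(kAmp = kAmp, cMin = cMin, annulusPx = as.integer(annulusPx),
                 magFloorFrac = magFloorFrac, sdCapCms = sdCapCms),
            class = "flowParams")
}

#' Segment the CSF region of interest from velocity dynamics
#'
#' Velocity-spectrum segmentation: a pixel belongs to the CSF ROI if its
#' temporal peak-to-peak velocity amplitude exceeds \code{kAmp} times the
#' background amplitude (median over the frame) and its waveform correlates
#' with the seed pixel's waveform at \code{cMin} or better. The connected
#' component containing the seed is returned as a fixed (time-invariant)
#' ROI.
#'
#' @param series a \code{CinePCSeries}
#' @param seedPx 0-based pixel coordinates of a seed inside the lumen
#' @param params a \code{\link{flowParams}}
#' @return logical ROI mask
#' @export
segmentCsfRoi <- function(series, seedPx, params = flowParams()) {
  stopifnot(is(series, "CinePCSeries"))
  v <- series@velocityCms
  amp <- apply(v, c(1, 2), function(w) diff(range(w)))
  bgPix <- median(amp)   # typical single-pixel (noise) amplitude
  if (max(amp) <= max(bgPix * params$kAmp, 1e-9) || max(amp) < 1e-9)
    stop("no dynamic pixels: velocity field looks static")
  seedW <- v[round(seedPx[1]) + 1, round(seedPx[2]) + 1, ]
  if (var(seedW) <= 0) stop("seed pixel has a flat waveform")
  # background amplitude: peak-to-peak of the spatially averaged (median)
  # waveform, in which uncorrelated pixel noise cancels; this keeps the
  # amplitude criterion from clipping the slow lumen rim while the
  # correlation criterion does the discriminative work
  bgWave <- apply(v, 3, median)
  ampFloor <- params$kAmp * diff(range(bgWave))
  nt <- dim(v)[3]
  vm <- matrix(v, ncol = nt)
  cc <- as.vector(suppressWarnings(cor(t(vm), seedW)))
  cc[is.na(cc)] <- 0
  cand <- amp >= ampFloor &
    matrix(cc >= params$cMin, nrow(amp), ncol(amp))
  if (!any(cand)) stop("empty CSF ROI")
  componentContaining(cand, seedPx)
}

#' Temporal de-aliasing of wrapped velocities
#'
#' Unwraps each pixel waveform in time: a frame-to-frame jump larger than
#' VENC is interpreted as a single wrap by 2 VENC and removed. Waveforms
#' whose accumulated wrap offset does not return to zero over the cycle are
#' counted in the \code{residualWraps} attribute (QC).
#'
#' @param series a \code{CinePCSeries}
#' @return the series with unwrapped velocities; attribute
#'   \code{residualWraps} on the velocity array gives the QC count
#' @export
dealias <- function(series) {
  stopifnot(is(series, "CinePCSeries"))
  v <- series@velocityCms
  venc <- series@vencCms
  nt <- dim(v)[3]
  vm <- matrix(v, ncol = nt)           # pixels x time
  d <- vm[, -1, drop = FALSE] - vm[, -nt, drop = FALSE]
  wrap <- -2 * venc * sign(d) * (abs(d) > venc)
  offset <- cbind(0, t(apply(wrap, 1, cumsum)))
  un <- vm + offset
  residual <- sum(abs(offset[, nt]) > 1e-9)
  out <- array(un, dim = dim(v))
  attr(out, "residualWraps") <- residual
  series@velocityCms <- out
  series
}

#' Background phase (velocity offset) correction
#'
#' Identifies static tissue in an annulus around the ROI (dilation minus
#' ROI) with magnitude above a floor and temporal velocity SD below a cap,
#' and subtracts its time-mean velocity from all frames so that static
#' tissue defines the zero-velocity reference.
#'
#' @param series a \code{CinePCSeries}
#' @param roi logical CSF ROI mask
#' @param params a \code{\link{flowParams}}
#' @return the corrected series; the applied offset (cm/s) is stored in
#'   attribute \code{offsetApplied} of the velocity array (0 with a warning
#'   when no static tissue is found)
#' @export
correctBackground <- function(series, roi, params = flowParams()) {
  stopifnot(is(series, "CinePCSeries"))
  kern <- EBImage::makeBrush(2L * params$annulusPx + 1L, shape = "disc")
  dil <- EBImage::dilate(roi * 1, kern) > 0
  ring <- dil & !roi
  magMean <- apply(series@magnitude, c(1, 2), mean)
  velSd <- apply(series@velocityCms, c(1, 2), sd)
  floorVal <- params$magFloorFrac * quantile(magMean, 0.99)
  static <- ring & magMean >= floorVal & velSd <= params$sdCapCms
  if (!any(static)) {
    warning("no static tissue found around the ROI; no correction applied")
    attr(series@velocityCms, "offsetApplied") <- 0
    return(series)
  }
  nt <- dim(series@velocityCms)[3]
  vm <- matrix(series@velocityCms, ncol = nt)
  offset <- mean(vm[as.vector(static), ])
  out <- series@velocityCms - offset
  attr(out, "offsetApplied") <- offset
  series@velocityCms <- out
  series
}

#' Flow-rate curve over the ROI
#'
#' Per frame, flow rate = ROI area times the mean velocity inside the ROI,
#' converted from cm/s to mm/s. Sample times are \code{(k-1)/n * cycleMs}.
#'
#' @param series a \code{CinePCSeries}
#' @param mask logical ROI mask
#' @return a \code{FlowCurve} in mm^3/s
#' @export
computeFlowCurve <- function(series, mask) {
  stopifnot(is(series, "CinePCSeries"), any(mask))
  nt <- dim(series@velocityCms)[3]
  vm <- matrix(series@velocityCms, ncol = nt)
  meanV <- colMeans(vm[as.vector(mask), , drop = FALSE])
  area <- sum(mask) * series@pixelAreaMm2
  new("FlowCurve", timesMs = (seq_len(nt) - 1) / nt * series@cycleMs,
      flowMm3s = area * meanV * 10, roiAreaMm2 = area,
      cycleMs = series@cycleMs)
}

#' Directional stroke volumes of a flow curve
#'
#' Integrates the positive and negative parts of the flow curve over one
#' cardiac cycle by the periodic trapezoid rule (the segment from the last
#' sample back to the first closes the cycle). \code{sv} is the mean of the
#' two directional volumes.
#'
#' @param curve a \code{FlowCurve}
#' @return a \code{StrokeVolume} (mm^3)
#' @export
strokeVolume <- function(curve) {
  stopifnot(is(curve, "FlowCurve"))
  q <- curve@flowMm3s
  t <- curve@timesMs
  qc <- c(q, q[1])
  tc <- c(t, t[1] + curve@cycleMs)
  dt <- diff(tc) / 1000
  trapz <- function(y) sum(dt * (head(y, -1) + tail(y, -1)) / 2)
  svPos <- trapz(pmax(qc, 0))
  svNeg <- abs(trapz(pmin(qc, 0)))
  new("StrokeVolume", svPosMm3 = svPos, svNegMm3 = svNeg,
      svMm3 = (svPos + svNeg) / 2)
}

#' Stroke-volume ratio and cardiac-cycle-mismatch QC
#'
#' Ratio-SV = SV at the aqueduct divided by SV at the cervical (C2-C3)
#' level. The signed cycle mismatch between the two series is
#' \code{(cycleAq - cycleCv) / mean(cycles) * 100}; subjects with
#' |mismatch| above the QC limit (10%) are flagged for exclusion.
#'
#' @param svAq,svCv \code{StrokeVolume} objects (or numeric SVs in mm^3)
#' @param cycleAqMs,cycleCvMs cardiac cycle durations of the two series, ms
#' @param mismatchLimitPct QC limit in percent (default 10)
#' @return list with \code{svAqMm3}, \code{svCvMm3}, \code{ratio}
#'   (fraction), \code{ratioPct}, \code{cycleMismatchPct}, \code{flagged}
#' @export
ratioSV <- function(svAq, svCv, cycleAqMs, cycleCvMs,
                    mismatchLimitPct = 10) {
  getSv <- function(x) if (is(x, "StrokeVolume")) x@svMm3 else as.numeric(x)
  a <- getSv(svAq); c <- getSv(svCv)
  if (c <= 0) stop("cervical stroke volume must be positive")
  mismatch <- (cycleAqMs - cycleCvMs) / mean(c(cycleAqMs, cycleCvMs)) * 100
  list(svAqMm3 = a, svCvMm3 = c, ratio = a / c, ratioPct = a / c * 100,
       cycleMismatchPct = mismatch,
       flagged = abs(mismatch) > mismatchLimitPct)
}

#' Full flow pipeline for one cine site
#'
#' Segments the CSF ROI, de-aliases, applies background correction,
#' computes the flow curve and the stroke volumes.
#'
#' @param series a \code{CinePCSeries}
#' @param seedPx seed pixel inside the lumen (0-based)
#' @param params a \code{\link{flowParams}}
#' @return list with \code{roi}, \code{curve}, \code{sv},
#'   \code{offsetApplied}, \code{residualWraps}
#' @export
analyzeFlowSite <- function(series, seedPx, params = flowParams()) {
  # de-alias before segmenting so waveform correlation with the seed pixel
  # operates on physical velocities rather than wrapped ones
  series <- dealias(series)
  residual <- attr(series@velocityCms, "residualWraps")
  roi <- segmentCsfRoi(series, seedPx, params)
  series <- correctBackground(series, roi, params)
  offset <- attr(series@velocityCms, "offsetApplied")
  curve <- computeFlowCurve(series, roi)
  list(roi = roi, curve = curve, sv = strokeVolume(curve),
       offsetApplied = offset, residualWraps = residual)
}
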