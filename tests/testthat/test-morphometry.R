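# Morphometry: interpolation, gradient thresholding, ROI binarization,
# Ratio-Area measurement and slice selection.

test_that("bilinear interpolation preserves constants, ramps and extent", {
  img <- image2d(matrix(7, 11, 11), 1)
  fine <- interpolateToResolution(img, 0.25)
  expect_true(all(abs(fine - 7) < 1e-12))

  ramp <- image2d(matrix(rep(0:10, 11), 11, 11), 1)
  fineR <- interpolateToResolution(ramp, 0.5)
  # interior fine pixels sit exactly on the linear ramp
  expect_equal(fineR[5, 5], (5 - 1) * 0.5, tolerance = 1e-12)
  expect_equal(fineR[14, 3], (14 - 1) * 0.5, tolerance = 1e-12)

  chk <- image2d(matrix((0:20 %% 2), 21, 15), 0.8)
  fineC <- interpolateToResolution(chk, 0.2)
  extentSrc <- (dim(chk) - 1) * pixelSpacing(chk)
  extentDst <- (dim(fineC) - 1) * pixelSpacing(fineC)
  expect_true(all(abs(extentSrc - extentDst) <= 0.2 + 1e-9))
})

test_that("interpolation preconditions are enforced", {
  img <- image2d(matrix(0, 5, 5), 1)
  expect_error(interpolateToResolution(img, 2), "source spacing")
  expect_error(interpolateToResolution(img, 0.005), "factor > 100")
})

test_that("max-gradient threshold finds step, ramp midpoint and blurred edge", {
  step <- image2d(cbind(matrix(10, 20, 9), matrix(100, 20, 11)), 0.5)
  thr <- thresholdMaxGradient(step, rbind(c(10, 2), c(10, 17)))
  expect_gte(thr, 10); expect_lte(thr, 100)
  expect_equal(thr, 55, tolerance = 5)

  # smooth circular edge: threshold should sit at the half-maximum
  xs <- 0:100 - 50
  d <- sqrt(outer(xs^2, xs^2, "+"))
  blur <- image2d(10 + 90 * pnorm((30 - d) / 2), 0.5)
  thrB <- thresholdMaxGradient(blur, rbind(c(50, 50), c(95, 50)))
  expect_equal(thrB, 55, tolerance = 3)

  flat <- image2d(matrix(3, 10, 10), 1)
  expect_error(thresholdMaxGradient(flat, rbind(c(1, 5), c(8, 5))), "flat")
})

test_that("binarizeRegion labels, polarity warning, and extremes", {
  img <- image2d(matrix(runif(400, 10, 100), 20, 20), 1)
  roi <- rbind(c(2, 2), c(17, 2), c(17, 17), c(2, 17))
  lab <- binarizeRegion(img, roi, 55, "dark")
  inside <- !is.na(lab)
  expect_true(all(lab[inside] == (img[inside] >= 55)))
  expect_true(all(is.na(lab[1, ])))

  expect_true(all(suppressWarnings(binarizeRegion(img, roi, 5, "dark")) == 1,
                  na.rm = TRUE))
  expect_warning(labHi <- binarizeRegion(img, roi, 200, "bright"), "empty")
  expect_true(all(labHi == 0, na.rm = TRUE))
})

test_that("dark-ellipse mask area from the pipeline is within 2% of analytic", {
  f <- brainMorph()
  gtSlice <- f$gt$perSlice[1, ]
  expect_lt(abs(f$res@areaVentMm2 / gtSlice$areaVentMm2 - 1), 0.02)
  expect_lt(abs(f$res@areaBrainMm2 / gtSlice$areaBrainMm2 - 1), 0.02)
  expect_lt(abs(f$res@ratioArea / gtSlice$ratioArea - 1), 0.02)
})

test_that("plexus exclusion removes its analytic area from Area-vent", {
  f <- brainMorph()
  vol0 <- generateBrainSlice(brainPhantomSpec(plexusRadiusMm = 0,
                                              nSlices = 1, peakSlice = 1))
  gt0 <- groundTruth(vol0)
  res0 <- selectMaxRatioSlice(vol0, gt0$rois,
                              thresholdLine = gt0$rois$thresholdLine)
  expect_equal(res0@areaVentMm2 - f$res@areaVentMm2, pi * 2^2,
               tolerance = 0.1)
})

test_that("measureRatioArea contract: exact ratio, empty cases, errors", {
  vent <- matrix(NA_integer_, 10, 10); vent[3:8, 3:8] <- 1L
  vent[4:6, 4:6] <- 0L
  brain <- matrix(1L, 10, 10)
  r <- measureRatioArea(vent, brain, NULL, pixelAreaMm2 = 0.25)
  expect_equal(r@areaVentMm2, 9 * 0.25)
  expect_equal(r@ratioArea, r@areaVentMm2 / r@areaBrainMm2)

  ventNone <- matrix(1L, 10, 10)
  expect_equal(measureRatioArea(ventNone, brain, NULL, 1)@ratioArea, 0)
  expect_error(measureRatioArea(vent, matrix(0L, 10, 10), NULL, 1),
               "zero brain")
})

test_that("slice selection maximizes Ratio-Area with lowest-index ties", {
  vol <- generateBrainSlice(brainPhantomSpec(nSlices = 5, peakSlice = 4,
                                             noiseSd = 1))
  gt <- groundTruth(vol)
  res <- selectMaxRatioSlice(vol, gt$rois,
                             thresholdLine = gt$rois$thresholdLine)
  expect_equal(res@sliceIndex, 4L)

  one <- generateBrainSlice(brainPhantomSpec(nSlices = 1, peakSlice = 1))
  r1 <- selectMaxRatioSlice(one, groundTruth(one)$rois,
                            thresholdLine = groundTruth(one)$rois$thresholdLine)
  expect_equal(r1@sliceIndex, 1L)

  # equal slices: the tie goes to the lower index
  flat <- generateBrainSlice(brainPhantomSpec(nSlices = 2, peakSlice = 1,
                                              sliceScaleStep = 0))
  rf <- selectMaxRatioSlice(flat, groundTruth(flat)$rois,
                            thresholdLine = groundTruth(flat)$rois$thresholdLine)
  expect_equal(rf@sliceIndex, 1L)
})

test_that("ratio is invariant under intensity scaling and grid choice", {
  f <- brainMorph()
  scaled <- new("Volume3D", data = volData(f$vol) * 3 + 40,
                spacingMm = voxelSpacing(f$vol), groundTruth = list())
  resS <- selectMaxRatioSlice(scaled, f$gt$rois,
                              thresholdLine = f$gt$rois$thresholdLine)
  expect_equal(resS@ratioArea, f$res@ratioArea, tolerance = 1e-10)
  expect_equal(resS@thresholdUsed, f$res@thresholdUsed * 3 + 40,
               tolerance = 1e-6)

  resC <- selectMaxRatioSlice(f$vol, f$gt$rois, targetSpacingMm = 0.2,
                              thresholdLine = f$gt$rois$thresholdLine)
  expect_lt(abs(resC@ratioArea / f$res@ratioArea - 1), 0.02)
})

test_that("measured areas converge to analytic with native resolution", {
  errAt <- function(h) {
    vol <- generateBrainSlice(brainPhantomSpec(nSlices = 1, peakSlice = 1,
                                               spacingMm = h))
    gt <- groundTruth(vol)
    res <- selectMaxRatioSlice(vol, gt$rois,
                               thresholdLine = gt$rois$thresholdLine)
    abs(res@areaVentMm2 / gt$perSlice$areaVentMm2[1] - 1)
  }
  expect_lt(errAt(0.5), errAt(1.5))
})
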