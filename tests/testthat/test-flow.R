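# Flow module: ROI segmentation, de-aliasing, background correction, flow
# curves, stroke volumes and Ratio-SV with the cycle-mismatch QC.

centerSeed <- function(series) {
  rep((dim(series@magnitude)[1] - 1) / 2, 2)
}

test_that("velocity-spectrum ROI matches the phantom lumen", {
  # 0.45 mm spacing keeps grid points off the exact r = R circle, where
  # the parabolic profile is identically zero
  ser <- generateCineSeries(cinePhantomSpec(lumenRadiusMm = 2,
                                            voxelSpacingMm = 0.45))
  roi <- segmentCsfRoi(ser, centerSeed(ser))
  expect_lt(abs(sum(roi) * ser@pixelAreaMm2 / (pi * 4) - 1), 0.10)
  # static bright background is excluded
  expect_equal(sum(roi & !groundTruth(ser)$lumenMask), 0)

  # with noise the ROI still tracks the lumen
  serN <- generateCineSeries(cinePhantomSpec(lumenRadiusMm = 2,
                                             voxelSpacingMm = 0.45,
                                             noiseSdCms = 0.1))
  roiN <- segmentCsfRoi(serN, centerSeed(serN))
  expect_lt(abs(sum(roiN) * serN@pixelAreaMm2 / (pi * 4) - 1), 0.10)
  expect_lte(sum(roiN & !groundTruth(serN)$lumenMask), 2)

  still <- generateCineSeries(cinePhantomSpec(
    waveformFn = function(t) rep(0, length(t))))
  expect_error(segmentCsfRoi(still, centerSeed(still)), "static|flat")
})

test_that("background correction removes the injected offset", {
  ser <- generateCineSeries(cinePhantomSpec(backgroundOffsetCms = 0.5,
                                            noiseSdCms = 0.1, seed = 2L))
  roi <- segmentCsfRoi(ser, centerSeed(ser))
  corr <- correctBackground(ser, roi)
  expect_lt(abs(attr(corr@velocityCms, "offsetApplied") - 0.5), 0.02)
  # corrected lumen waveform matches the true (offset-free) one
  gt <- groundTruth(ser)
  ctr <- centerSeed(ser) + 1
  err <- corr@velocityCms[ctr[1], ctr[2], ] -
    (gt$trueVelocityCms[ctr[1], ctr[2], ] - 0.5)
  expect_lt(max(abs(err)), 0.4)   # bounded by the injected noise

  # noiseless: static tissue mean is exactly zero afterwards
  ser0 <- generateCineSeries(cinePhantomSpec(backgroundOffsetCms = 0.37))
  roi0 <- segmentCsfRoi(ser0, centerSeed(ser0))
  corr0 <- correctBackground(ser0, roi0)
  expect_equal(attr(corr0@velocityCms, "offsetApplied"), 0.37,
               tolerance = 1e-9)
  ring <- !groundTruth(ser0)$lumenMask
  expect_lt(max(abs(corr0@velocityCms[, , 1][ring])), 1e-9)

  # zero offset: correction below the noise floor
  serZ <- generateCineSeries(cinePhantomSpec(noiseSdCms = 0.1, seed = 3L))
  corrZ <- correctBackground(serZ, segmentCsfRoi(serZ, centerSeed(serZ)))
  expect_lt(abs(attr(corrZ@velocityCms, "offsetApplied")), 0.1)
})

test_that("de-aliasing restores wrapped waveforms and is idempotent", {
  al <- generateCineSeries(cinePhantomSpec(waveformAmpCms = 6, vencCms = 10,
                                           alias = TRUE))
  un <- dealias(al)
  gt <- groundTruth(al)
  expect_equal(max(un@velocityCms), 12, tolerance = 1e-6)
  expect_lt(max(abs(un@velocityCms - gt$trueVelocityCms)), 1e-9)

  twice <- dealias(un)
  expect_equal(as.vector(twice@velocityCms), as.vector(un@velocityCms))

  noal <- generateCineSeries(cinePhantomSpec(waveformAmpCms = 3))
  expect_equal(as.vector(dealias(noal)@velocityCms),
               as.vector(noal@velocityCms))
})

test_that("aliased sinusoid at 1.2 VENC is recovered to < 5% RMS", {
  specA <- cinePhantomSpec(waveformAmpCms = 6, vencCms = 10, alias = TRUE,
                           noiseSdCms = 0.1, seed = 4L)
  specB <- cinePhantomSpec(waveformAmpCms = 6, vencCms = 10, alias = FALSE,
                           noiseSdCms = 0.1, seed = 4L)
  fa <- analyzeFlowSite(generateCineSeries(specA),
                        centerSeed(generateCineSeries(specA)))
  fb <- analyzeFlowSite(generateCineSeries(specB),
                        centerSeed(generateCineSeries(specB)))
  rms <- sqrt(mean((fa$curve@flowMm3s - fb$curve@flowMm3s)^2))
  expect_lt(rms / max(abs(fb$curve@flowMm3s)), 0.05)
})

test_that("flow curve is ROI area times mean velocity with unit conversion", {
  ser <- generateCineSeries(cinePhantomSpec(
    waveformFn = function(t) rep(0, length(t)), backgroundOffsetCms = 1))
  mask <- matrix(FALSE, dim(ser@magnitude)[1], dim(ser@magnitude)[2])
  mask[1:20, 1:20] <- TRUE     # any fixed ROI; uniform 1 cm/s everywhere
  curve <- computeFlowCurve(ser, mask)
  expect_equal(unique(round(curve@flowMm3s, 9)),
               curve@roiAreaMm2 * 1 * 10)

  # parabolic profile integrates like its mean velocity over the lumen
  ser2 <- generateCineSeries(cinePhantomSpec(waveformAmpCms = 3))
  gt <- groundTruth(ser2)
  curve2 <- computeFlowCurve(ser2, gt$lumenMask)
  expected <- gt$lumenAreaMm2 * gt$vbarCms * 10
  expect_lt(max(abs(curve2@flowMm3s - expected)) / max(abs(expected)), 0.02)
})

test_that("stroke volume integrates the closed-form sinusoid", {
  n <- 32
  t <- (seq_len(n) - 1) / n * 1000
  q <- pi * sin(2 * pi * t / 1000)
  curve <- new("FlowCurve", timesMs = t, flowMm3s = q, roiAreaMm2 = 1,
               cycleMs = 1000)
  sv <- strokeVolume(curve)
  expect_lt(abs(sv@svPosMm3 - 1), 0.005)
  expect_lt(abs(sv@svNegMm3 - 1), 0.005)
  expect_lt(abs(sv@svMm3 - 1), 0.005)

  zero <- new("FlowCurve", timesMs = t, flowMm3s = rep(0, n),
              roiAreaMm2 = 1, cycleMs = 1000)
  svz <- strokeVolume(zero)
  expect_identical(c(svz@svPosMm3, svz@svNegMm3, svz@svMm3), c(0, 0, 0))

  # offset shifts the directional difference by offset * T
  off <- new("FlowCurve", timesMs = t, flowMm3s = q + 0.5, roiAreaMm2 = 1,
             cycleMs = 1000)
  svo <- strokeVolume(off)
  expect_lt(abs((svo@svPosMm3 - svo@svNegMm3) - 0.5 * 1), 0.01)
})

test_that("ratioSV arithmetic and mismatch QC", {
  r <- ratioSV(30, 600, 850, 850)
  expect_equal(r$ratioPct, 5)
  expect_equal(r$cycleMismatchPct, 0)
  expect_false(r$flagged)

  r2 <- ratioSV(30, 600, 900, 800)
  expect_equal(r2$cycleMismatchPct, 100 / 850 * 100, tolerance = 1e-9)
  expect_true(r2$flagged)
  expect_error(ratioSV(30, 0, 850, 850), "positive")
})

test_that("stroke volume is recovered within 5% across the phantom grid", {
  cases <- expand.grid(A = c(1, 5), T = c(700, 1000), R = c(1, 3))
  cases <- rbind(cases, data.frame(A = 3, T = 850, R = 2))
  for (i in seq_len(nrow(cases))) {
    spec <- cinePhantomSpec(waveformAmpCms = cases$A[i],
                            cycleMs = cases$T[i],
                            lumenRadiusMm = cases$R[i],
                            noiseSdCms = 0.3, vencCms = 12, seed = 10L + i)
    ser <- generateCineSeries(spec)
    f <- analyzeFlowSite(ser, centerSeed(ser))
    expect_lt(abs(f$sv@svMm3 / groundTruth(ser)$svMm3 - 1), 0.05)
  }
})

test_that("Ratio-SV is invariant to cardiac-cycle changes at fixed SV", {
  ratioAt <- function(scale) {
    # hold each site's SV fixed while the cycle scales: A ~ 1/T
    aq <- cinePhantomSpec(cycleMs = 850 * scale,
                          waveformAmpCms = 3 / scale, lumenRadiusMm = 1.8,
                          noiseSdCms = 0.1, seed = 21L)
    cv <- cinePhantomSpec(cycleMs = 850 * scale,
                          waveformAmpCms = 1.5 / scale, lumenRadiusMm = 5,
                          noiseSdCms = 0.1, voxelSpacingMm = 0.6,
                          fovMm = 30, vencCms = 5, seed = 22L)
    sAq <- generateCineSeries(aq); sCv <- generateCineSeries(cv)
    fAq <- analyzeFlowSite(sAq, centerSeed(sAq))
    fCv <- analyzeFlowSite(sCv, centerSeed(sCv))
    ratioSV(fAq$sv, fCv$sv, sAq@cycleMs, sCv@cycleMs)$ratioPct
  }
  r <- vapply(c(0.8, 1, 1.2), ratioAt, numeric(1))
  expect_lt(max(abs(r / r[2] - 1)), 0.02)
})
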