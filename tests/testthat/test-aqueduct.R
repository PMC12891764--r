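# Aqueduct module: MIP, binarization, centerline, microchannels,
# Poiseuille resistance and the cumulative-resistance endpoint.

test_that("Poiseuille closed form and D^4 scaling are exact", {
  p1 <- poiseuilleResistance(profileFromDiameters(10, 1))
  expect_equal(p1@totalResistance, 128 * 0.71 * 10 / pi, tolerance = 1e-12)

  p2 <- poiseuilleResistance(profileFromDiameters(10, 2))
  expect_equal(p1@totalResistance / p2@totalResistance, 16,
               tolerance = 1e-12)

  # stored resistances recompute exactly from stored L, D, mu
  mc <- microchannels(poiseuilleResistance(
    profileFromDiameters(12, seq(1, 2, length.out = 50))))
  expect_equal(mc$resistance,
               128 * 0.71 * mc$lengthMm / (pi * mc$diameterMm^4),
               tolerance = 1e-14)
  expect_equal(mc$cumResistance, cumsum(mc$resistance), tolerance = 1e-14)
})

test_that("n = 100 midpoint decomposition matches dense quadrature on a taper", {
  fn <- function(s) 1 + 0.5 * s
  D <- fn((seq_len(100) - 0.5) / 100)
  prof <- poiseuilleResistance(profileFromDiameters(10, D))
  oracle <- poiseuilleQuadrature(fn, 10)
  expect_lt(abs(prof@totalResistance / oracle - 1), 0.01)
})

test_that("effective endpoint standardizes the distal end", {
  uni <- effectiveEndpoint(poiseuilleResistance(
    profileFromDiameters(15, rep(2, 100))))
  expect_equal(uni@endpointIndex, 95L)
  expect_lt(abs(uni@effectiveLengthMm - 0.95 * 15), 0.15 + 1e-9)

  # narrow (D=1, 5 mm) then wide (D=3, 10 mm): R1 ~ 144.6 dominates, so
  # the 95% point falls inside the narrow section
  D <- c(rep(1, 40), rep(3, 60))
  L <- c(rep(5 / 40, 40), rep(10 / 60, 60))
  mc <- data.frame(i = 1:100, lengthMm = L, diameterMm = D,
                   resistance = NA_real_, cumResistance = NA_real_)
  prof <- new("AqueductProfile", microchannels = mc,
              centerlineMm = cbind(0:100, 0), userLengthMm = 15,
              endpointIndex = NA_integer_, effectiveLengthMm = NA_real_,
              totalResistance = NA_real_, effectiveResistance = NA_real_,
              dMeanMm = NA_real_, dMinMm = NA_real_,
              params = unclass(resistanceParams()))
  prof <- effectiveEndpoint(poiseuilleResistance(prof))
  expect_lt(prof@effectiveLengthMm, 5)
  expect_equal(prof@dMinMm, 1)

  full <- effectiveEndpoint(poiseuilleResistance(
    profileFromDiameters(15, rep(2, 100))),
    resistanceParams(endpointFraction = 1))
  expect_equal(full@endpointIndex, 100L)
  expect_equal(full@effectiveLengthMm, 15, tolerance = 1e-9)

  # minimality: no shorter prefix reaches the cutoff
  cum <- microchannels(prof)$cumResistance
  k <- prof@endpointIndex
  expect_gte(cum[k], 0.95 * prof@totalResistance - 1e-9)
  if (k > 1) expect_lt(cum[k - 1], 0.95 * prof@totalResistance)
})

test_that("MIP projection has max semantics", {
  a <- array(0, dim = c(6, 6, 3))
  a[2, 2, 1] <- 5; a[5, 5, 2] <- 7
  vol <- new("Volume3D", data = a, spacingMm = c(1, 1, 1),
             groundTruth = list())
  one <- mipProject(vol, c(2, 2))
  expect_equal(as.vector(one), as.vector(a[, , 2]))
  all3 <- mipProject(vol)
  expect_equal(all3[2, 2], 5)
  expect_equal(all3[5, 5], 7)
  expect_error(mipProject(vol, c(3, 2)), "slab")
  # projected lumen is at least as wide as any single slice's
  tube <- generateTubeVolume(tubePhantomSpec(lengthMm = 6, diameterMm = 1.5,
                                             voxelSpacingMm = 0.2))
  proj <- mipProject(tube)
  midZ <- (dim(volData(tube))[3] + 1) %/% 2
  expect_true(all(proj >= volData(tube)[, , midZ]))
})

test_that("binarization keeps the component containing the guide line", {
  tube <- generateTubeVolume(tubePhantomSpec(lengthMm = 10, diameterMm = 2,
                                             voxelSpacingMm = 0.06))
  gt <- groundTruth(tube)
  proj <- mipProject(tube)
  # speckle far from the lumen, above threshold
  proj[3, 3] <- 100
  mask <- binarizeAqueduct(proj, gt$landmarks$narrowLinePx,
                           targetSpacingMm = 0.03)
  sp <- pixelSpacing(mask)
  expect_false(mask[round(3 * 0.06 / sp[1]) + 1,
                    round(3 * 0.06 / sp[2]) + 1])
  # mask area close to the analytic projection (L x D rectangle)
  expect_lt(abs(sum(mask) * prod(sp) / (10 * 2) - 1), 0.05)
})

test_that("centerline is straight for a straight tube and errors cleanly", {
  tube <- generateTubeVolume(tubePhantomSpec(lengthMm = 10, diameterMm = 2,
                                             voxelSpacingMm = 0.1))
  gt <- groundTruth(tube)
  proj <- mipProject(tube)
  mask <- binarizeAqueduct(proj, gt$landmarks$narrowLinePx,
                           targetSpacingMm = 0.05)
  sp0 <- pixelSpacing(proj); sp <- pixelSpacing(mask)
  sc <- function(p) p * sp0 / sp
  cl <- extractCenterline(mask, sc(gt$landmarks$startPx),
                          sc(gt$landmarks$endPx))
  yAxisMm <- gt$landmarks$startPx[2] * sp0[2]
  rms <- sqrt(mean((cl$pointsMm[, 2] - yAxisMm)^2))
  expect_lt(rms, 0.05 / 2)   # half an analysis pixel

  expect_error(extractCenterline(mask, sc(gt$landmarks$startPx),
                                 sc(gt$landmarks$startPx)), "coincide")
  # disconnected mask between the points
  cut <- mask
  cut[round(nrow(mask) / 2) + (-2:2), ] <- FALSE
  cut <- image2d(cut, sp)
  expect_error(extractCenterline(cut, sc(gt$landmarks$startPx),
                                 sc(gt$landmarks$endPx)), "disconnected")
})

test_that("bent-tube centerline recovers the ground-truth arc length", {
  tube <- generateTubeVolume(tubePhantomSpec(lengthMm = 12, diameterMm = 1.5,
                                             bendAngleDeg = 90,
                                             voxelSpacingMm = 0.1))
  gt <- groundTruth(tube)
  prof <- analyzeAqueduct(tube, gt$landmarks,
                          resistanceParams(targetSpacingMm = 0.05))
  expect_lt(abs(prof@userLengthMm / 12 - 1), 0.03)
})

test_that("microchannel diameters track the phantom profile", {
  cyl <- fineCylinder()
  mc <- microchannels(cyl$prof)
  expect_true(all(abs(mc$diameterMm - 2) <= 0.03 + 1e-9))
  expect_equal(sum(mc$lengthMm), cyl$prof@userLengthMm, tolerance = 1e-9)

  tap <- fineTaper()
  mcT <- microchannels(tap$prof)
  sMid <- (cumsum(mcT$lengthMm) - mcT$lengthMm / 2) / sum(mcT$lengthMm)
  truth <- 1 + 0.5 * sMid
  interior <- 5:95
  expect_true(all(abs(mcT$diameterMm - truth)[interior] <= 0.05))
})

test_that("summary reports diameters and the D^-4 law end to end", {
  cyl <- fineCylinder()
  s <- summarizeAqueduct(cyl$prof)
  expect_lt(abs(s$d_mean_mm - 2), 0.03 + 1e-9)
  expect_lt(abs(s$d_min_mm - 2), 0.03 + 1e-9)

  tap <- fineTaper()
  sT <- summarizeAqueduct(tap$prof)
  mcT <- microchannels(tap$prof)
  expect_equal(which.min(mcT$diameterMm[seq_len(tap$prof@endpointIndex)]),
               which(mcT$diameterMm == sT$d_min_mm)[1])
  expect_lte(sT$d_min_mm, sT$d_mean_mm)

  # halving all diameters multiplies resistance by 16 (within imaging
  # error; gently bent tubes so the edge quantization phase varies along
  # the lumen instead of repeating identically in every cross-section)
  runBent <- function(D) {
    v <- generateTubeVolume(tubePhantomSpec(lengthMm = 15, diameterMm = D,
                                            bendAngleDeg = 20,
                                            voxelSpacingMm = 0.03))
    analyzeAqueduct(v, groundTruth(v)$landmarks, resistanceParams())
  }
  expect_lt(abs(runBent(1)@effectiveResistance /
                  runBent(2)@effectiveResistance / 16 - 1), 0.05)
})

test_that("pipeline resistance converges to the quadrature oracle", {
  errAt <- function(h) {
    vol <- generateTubeVolume(tubePhantomSpec(lengthMm = 15, diameterMm = 2,
                                              voxelSpacingMm = h))
    gt <- groundTruth(vol)
    prof <- analyzeAqueduct(vol, gt$landmarks,
                            resistanceParams(targetSpacingMm = h))
    abs(prof@totalResistance / (0.71 * gt$poiseuilleIntegralPerMu) - 1)
  }
  errs <- vapply(c(0.12, 0.06, 0.03), errAt, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.05)
})
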