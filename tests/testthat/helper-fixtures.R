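# Shared fixtures, built lazily once per test run. The fine-grid tube
# analyses are the most expensive steps, so several test files reuse them.

.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtureEnv[[name]])) .fixtureEnv[[name]] <- build()
  .fixtureEnv[[name]]
}

# Uniform cylinder D = 2 mm, L = 15 mm on the 0.03 mm analysis grid,
# analyzed by the full aqueduct pipeline.
fineCylinder <- function() fixture("fineCylinder", function() {
  vol <- generateTubeVolume(
    tubePhantomSpec(lengthMm = 15, diameterMm = 2, voxelSpacingMm = 0.03))
  gt <- groundTruth(vol)
  prof <- analyzeAqueduct(vol, gt$landmarks, resistanceParams())
  list(gt = gt, prof = prof)
})

# Linear taper D(s) = 1 + 0.5 s over 10 mm on the same grid.
fineTaper <- function() fixture("fineTaper", function() {
  vol <- generateTubeVolume(
    tubePhantomSpec(lengthMm = 10, diameterMm = function(s) 1 + 0.5 * s,
                    voxelSpacingMm = 0.03))
  gt <- groundTruth(vol)
  prof <- analyzeAqueduct(vol, gt$landmarks, resistanceParams())
  list(gt = gt, prof = prof)
})

# Single-slice brain phantom (with plexus) plus its morphometry result.
brainMorph <- function() fixture("brainMorph", function() {
  spec <- brainPhantomSpec(plexusRadiusMm = 2, nSlices = 1L, peakSlice = 1L)
  vol <- generateBrainSlice(spec)
  gt <- groundTruth(vol)
  res <- selectMaxRatioSlice(vol, gt$rois,
                             thresholdLine = gt$rois$thresholdLine)
  list(vol = vol, gt = gt, res = res)
})

# One complete phantom subject written to disk.
phantomSubject <- function() fixture("phantomSubject", function() {
  dir <- file.path(tempdir(), "aqueflow-subject")
  rec <- makePhantomSubject(dir, "P01", sex = "M", age = 27, seed = 11L)
  list(dir = dir, record = rec)
})

# Build an AqueductProfile directly from a diameter sequence (bypassing
# imaging) for closed-form resistance tests.
profileFromDiameters <- function(lengthMm, diameters, muMPaS = 0.71,
                                 endpointFraction = 0.95) {
  n <- length(diameters)
  mc <- data.frame(i = seq_len(n), lengthMm = rep(lengthMm / n, n),
                   diameterMm = diameters, resistance = NA_real_,
                   cumResistance = NA_real_)
  new("AqueductProfile", microchannels = mc,
      centerlineMm = cbind(seq(0, lengthMm, length.out = n + 1), 0),
      userLengthMm = lengthMm, endpointIndex = NA_integer_,
      effectiveLengthMm = NA_real_, totalResistance = NA_real_,
      effectiveResistance = NA_real_, dMeanMm = NA_real_,
      dMinMm = NA_real_,
      params = unclass(resistanceParams(muMPaS = muMPaS, nSegments = max(n, 2),
                                        endpointFraction = endpointFraction)))
}

# Dense-quadrature oracle for the Poiseuille integral of a diameter
# profile: R = 128 mu / pi * int ds / D(s)^4, evaluated at nq points.
poiseuilleQuadrature <- function(diameterFn, lengthMm, muMPaS = 0.71,
                                 nq = 1e5) {
  s <- seq(0, 1, length.out = nq)
  y <- 128 * muMPaS / (pi * diameterFn(s)^4)
  sum(diff(s * lengthMm) * (head(y, -1) + tail(y, -1)) / 2)
}

# Exact two-sided Wilcoxon rank-sum p by enumeration of all group
# assignments (midranks; deviation-from-expectation definition).
exactWilcoxonP <- function(a, b) {
  pooled <- c(a, b)
  N <- length(pooled); nA <- length(a)
  r <- rank(pooled)
  combs <- utils::combn(N, nA)
  Ws <- colSums(matrix(r[combs], nrow = nA))
  Wobs <- sum(r[seq_len(nA)])
  E <- nA * (N + 1) / 2
  mean(abs(Ws - E) >= abs(Wobs - E) - 1e-9)
}
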