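# Synthetic phantom generators with closed-form ground truth. These define
# the study conditions the analysis pipelines are validated under: tube-like
# lumina on a dark background (aqueduct morphology), elliptical brain slices
# with dark ventricles and a bright choroid-plexus inclusion, cine velocity
# series with parabolic lumen profiles, and Table-1-scale cohort tables.
#
# Membership is decided by the voxel-center test (a voxel is lumen iff its
# center lies inside the analytic surface): deterministic and easy to check
# against closed-form volumes/areas. Noise is additive Gaussian.

#' Specification of a tube phantom
#'
#' Describes a tube-like lumen (emulating the cerebral aqueduct on a
#' high-contrast morphological acquisition): a planar centerline of given
#' length, a diameter profile along it, and image intensities. The default
#' spacing matches a reconstructed morphological grid (0.35 mm); fine grids
#' (e.g. 0.03 mm) can be requested for convergence studies.
#'
#' @param lengthMm centerline arc length in mm
#' @param diameterMm either a single diameter in mm or a function of the
#'   arc-length fraction \code{s} in [0,1] returning the diameter in mm
#' @param bendAngleDeg total in-plane bend of the centerline in degrees
#'   (0 = straight; 90 = quarter circle of radius \code{lengthMm}/angle)
#' @param voxelSpacingMm isotropic voxel spacing in mm
#' @param fgIntensity,bgIntensity lumen and background intensities
#' @param noiseSd additive Gaussian noise SD (intensity units)
#' @param marginMm padding between lumen and volume faces
#' @param fovMm optional explicit cross-sectional field of view; the lumen
#'   must fit inside it
#' @param seed RNG seed; identical spec + seed gives identical output
#' @return a validated spec (list of class \code{tubePhantomSpec})
#' @export
tubePhantomSpec <- function(lengthMm = 15, diameterMm = 2, bendAngleDeg = 0,
                            voxelSpacingMm = 0.35, fgIntensity = 100,
                            bgIntensity = 10, noiseSd = 0, marginMm = 1,
                            fovMm = NULL, seed = 1L) {
  diameterFn <- if (is.function(diameterMm)) diameterMm
  else {
    d <- diameterMm
    function(s) rep(d, length(s))
  }
  dTest <- diameterFn(seq(0, 1, length.out = 201))
  stopifnot(lengthMm > 0, voxelSpacingMm > 0, marginMm > 0, noiseSd >= 0)
  if (any(!is.finite(dTest)) || any(dTest <= 0))
    stop("diameter function must be positive on [0, 1]")
  maxD <- max(dTest)
  if (!is.null(fovMm) && maxD >= fovMm)
    stop("lumen wider than the field of view")
  structure(list(lengthMm = lengthMm, diameterFn = diameterFn,
                 bendAngleDeg = bendAngleDeg,
                 voxelSpacingMm = voxelSpacingMm, fgIntensity = fgIntensity,
                 bgIntensity = bgIntensity, noiseSd = noiseSd,
                 marginMm = marginMm, maxDiameterMm = maxD,
                 seed = as.integer(seed)),
            class = "tubePhantomSpec")
}

#' Generate a tube phantom volume
#'
#' Voxels whose center lies inside the swept-circle lumen get the foreground
#' intensity, all others the background intensity; Gaussian noise is added
#' on top. Ground truth (centerline, diameter profile, analytic lumen
#' volume, the Poiseuille integrand integral, and suggested analysis
#' landmarks) is attached to the returned \code{\link{Volume3D}}.
#'
#' @param spec a \code{\link{tubePhantomSpec}}
#' @return a \code{Volume3D}; \code{groundTruth(vol)} holds the analytic
#'   record
#' @export
generateTubeVolume <- function(spec) {
  stopifnot(inherits(spec, "tubePhantomSpec"))
  h <- spec$voxelSpacingMm
  L <- spec$lengthMm
  m <- spec$marginMm
  maxR <- spec$maxDiameterMm / 2
  set.seed(spec$seed)

  # planar centerline sampled densely in (x, y); z is the slab axis
  nsDense <- max(2001L, ceiling(L / (h / 4)))
  sFrac <- seq(0, 1, length.out = nsDense)
  theta <- spec$bendAngleDeg * pi / 180
  if (theta == 0) {
    clx <- m + sFrac * L
    cly <- rep(0, nsDense)
  } else {
    rho <- L / theta
    ang <- sFrac * theta
    clx <- m + rho * sin(ang)
    cly <- rho * (1 - cos(ang))
  }
  dProf <- spec$diameterFn(sFrac)

  # grid covering the centerline plus lumen radius and margin; odd pixel
  # counts keep the tube centered on voxel centers on straight phantoms
  xr <- range(clx) + c(-m - maxR, m + maxR)
  yr <- range(cly) + c(-m - maxR, m + maxR)
  nx <- ceiling(diff(xr) / h) + 1L
  ny <- ceiling(diff(yr) / h) + 1L
  nz <- 2L * ceiling((maxR + m) / h) + 1L
  if (ny %% 2L == 0L) ny <- ny + 1L
  x0 <- clx[1] - m - maxR
  y0 <- if (theta == 0) -((ny - 1L) / 2L) * h else yr[1]
  z0 <- 0
  zc <- ((nz - 1L) / 2L) * h
  xs <- x0 + (seq_len(nx) - 1) * h
  ys <- y0 + (seq_len(ny) - 1) * h
  zs <- z0 + (seq_len(nz) - 1) * h

  # in-plane squared distance to the centerline and local radius at the
  # nearest arc position, per (x, y) grid point
  if (theta == 0) {
    sNear <- pmin(pmax((xs - clx[1]) / L, 0), 1)
    inAxis <- xs >= clx[1] - 1e-9 & xs <= clx[1] + L + 1e-9
    r2xy <- outer(ifelse(inAxis, 0, Inf), ys^2, "+")
    Rxy <- matrix(spec$diameterFn(sNear) / 2, nx, ny)
  } else {
    # analytic distance to the circular-arc centerline: the arc has
    # center (m, rho) and spans polar angles [0, theta] measured from the
    # start point; points outside the sector snap to the nearer endpoint
    rho <- L / theta
    Cx <- m; Cy <- rho
    X <- matrix(xs, nx, ny); Y <- matrix(ys, nx, ny, byrow = TRUE)
    ang <- atan2(X - Cx, -(Y - Cy))
    rad <- sqrt((X - Cx)^2 + (Y - Cy)^2)
    sFracXY <- pmin(pmax(ang / theta, 0), 1)
    r2xy <- (rad - rho)^2
    below <- ang < 0
    r2xy[below] <- (X - clx[1])[below]^2 + (Y - cly[1])[below]^2
    above <- ang > theta
    r2xy[above] <- (X - clx[nsDense])[above]^2 +
      (Y - cly[nsDense])[above]^2
    Rxy <- matrix(spec$diameterFn(sFracXY) / 2, nx, ny)
  }

  vol <- array(spec$bgIntensity, dim = c(nx, ny, nz))
  R2 <- Rxy^2
  for (k in seq_len(nz)) {
    dz2 <- (zs[k] - zc)^2
    inside <- r2xy + dz2 <= R2
    sl <- vol[, , k]
    sl[inside] <- spec$fgIntensity
    vol[, , k] <- sl
  }
  if (spec$noiseSd > 0)
    vol <- vol + array(rnorm(length(vol), 0, spec$noiseSd), dim = dim(vol))

  # analytic ground truth
  sq <- seq(0, 1, length.out = 100001L)
  dq <- spec$diameterFn(sq)
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  volumeMm3 <- trapz(sq * L, pi * dq^2 / 4)
  poiseuillePerMu <- trapz(sq * L, 128 / (pi * dq^4))

  iNarrow <- which.min(dProf)
  tangent <- if (theta == 0) c(1, 0)
  else c(cos(sFrac[iNarrow] * theta), sin(sFrac[iNarrow] * theta))
  normal <- c(-tangent[2], tangent[1])
  half <- dProf[iNarrow] / 2 + m / 2
  pC <- c(clx[iNarrow], cly[iNarrow])
  toPx <- function(p) c((p[1] - x0) / h, (p[2] - y0) / h)
  gt <- list(
    kind = "tube", lengthMm = L, bendAngleDeg = spec$bendAngleDeg,
    profile = data.frame(sMm = sFrac * L, diameterMm = dProf),
    centerlineMm = cbind(x = clx, y = cly),
    volumeMm3 = volumeMm3,
    poiseuilleIntegralPerMu = poiseuillePerMu,
    landmarks = list(
      startPx = toPx(c(clx[1], cly[1])),
      endPx = toPx(c(clx[nsDense], cly[nsDense])),
      narrowLinePx = rbind(toPx(pC - half * normal),
                           toPx(pC + half * normal))),
    originMm = c(x0, y0, z0), seed = spec$seed)

  new("Volume3D", data = vol, spacingMm = rep(h, 3), groundTruth = gt)
}

#' Specification of a brain-slice phantom
#'
#' An elliptical bright "brain" containing two dark ventricle ellipses and,
#' optionally, a bright choroid-plexus disc inside the first ventricle. A
#' stack of slices is generated in which the ventricle size peaks at
#' \code{peakSlice}, so the slice with the maximal ventricle-to-brain ratio
#' is known by construction.
#'
#' @param brainAxesMm semi-axes (a, b) of the brain ellipse in mm
#' @param ventAxesMm semi-axes of each ventricle ellipse in mm
#' @param ventOffsetMm center offset of the ventricles from the brain
#'   center; the two ventricles sit at (-x, y) and (+x, y)
#' @param plexusRadiusMm radius of the bright plexus disc (0 = none)
#' @param plexusOffsetMm plexus center offset from the first ventricle center
#' @param nSlices,peakSlice slice count and the slice with maximal ventricles
#' @param sliceScaleStep per-slice shrink factor of the ventricle axes away
#'   from \code{peakSlice}
#' @param spacingMm in-plane pixel spacing in mm
#' @param sliceThicknessMm slice spacing in mm
#' @param brainIntensity,ventIntensity,bgIntensity,plexusIntensity image
#'   intensities
#' @param noiseSd additive Gaussian noise SD
#' @param seed RNG seed
#' @return a validated spec (list of class \code{brainPhantomSpec})
#' @export
brainPhantomSpec <- function(brainAxesMm = c(70, 55), ventAxesMm = c(10, 4),
                             ventOffsetMm = c(13.4, 5.7), plexusRadiusMm = 0,
                             plexusOffsetMm = c(0, 0), nSlices = 5L,
                             peakSlice = 3L, sliceScaleStep = 0.12,
                             spacingMm = 1, sliceThicknessMm = 2.2,
                             brainIntensity = 100, ventIntensity = 20,
                             bgIntensity = 0, plexusIntensity = 100,
                             noiseSd = 0, seed = 1L) {
  stopifnot(all(brainAxesMm > 0), all(ventAxesMm >= 0), spacingMm > 0,
            nSlices >= 1, peakSlice >= 1, peakSlice <= nSlices,
            plexusRadiusMm >= 0, noiseSd >= 0)
  if (any(ventAxesMm > 0)) {
    ang <- seq(0, 2 * pi, length.out = 73)
    for (sgn in c(-1, 1)) {
      bx <- sgn * ventOffsetMm[1] + ventAxesMm[1] * cos(ang)
      by <- ventOffsetMm[2] + ventAxesMm[2] * sin(ang)
      if (any((bx / brainAxesMm[1])^2 + (by / brainAxesMm[2])^2 >= 1))
        stop("ventricle ellipse not contained in the brain ellipse")
    }
    if (plexusRadiusMm > 0) {
      px <- plexusOffsetMm[1] + plexusRadiusMm * cos(ang)
      py <- plexusOffsetMm[2] + plexusRadiusMm * sin(ang)
      if (any((px / ventAxesMm[1])^2 + (py / ventAxesMm[2])^2 >= 1))
        stop("plexus disc not contained in the ventricle")
    }
  }
  structure(as.list(environment())[c(
    "brainAxesMm", "ventAxesMm", "ventOffsetMm", "plexusRadiusMm",
    "plexusOffsetMm", "nSlices", "peakSlice", "sliceScaleStep", "spacingMm",
    "sliceThicknessMm", "brainIntensity", "ventIntensity", "bgIntensity",
    "plexusIntensity", "noiseSd", "seed")],
    class = "brainPhantomSpec")
}

#' Generate a brain-slice phantom stack
#'
#' @param spec a \code{\link{brainPhantomSpec}}
#' @return a \code{Volume3D} whose ground truth holds per-slice analytic
#'   areas, the designated peak slice, and rough ROI polygons (0-based pixel
#'   coordinates) for the ventricles and the whole brain
#' @export
generateBrainSlice <- function(spec) {
  stopifnot(inherits(spec, "brainPhantomSpec"))
  set.seed(spec$seed)
  h <- spec$spacingMm
  a <- spec$brainAxesMm[1]; b <- spec$brainAxesMm[2]
  margin <- 5
  nx <- 2L * ceiling((a + margin) / h) + 1L
  ny <- 2L * ceiling((b + margin) / h) + 1L
  cx <- (nx - 1) / 2 * h; cy <- (ny - 1) / 2 * h
  xs <- (seq_len(nx) - 1) * h - cx
  ys <- (seq_len(ny) - 1) * h - cy
  X <- matrix(xs, nx, ny); Y <- matrix(ys, nx, ny, byrow = TRUE)
  inBrain <- (X / a)^2 + (Y / b)^2 <= 1

  vol <- array(spec$bgIntensity, dim = c(nx, ny, spec$nSlices))
  perSlice <- data.frame(slice = seq_len(spec$nSlices), scale = NA_real_,
                         areaVentMm2 = NA_real_, areaBrainMm2 = NA_real_,
                         ratioArea = NA_real_)
  va0 <- spec$ventAxesMm[1]; vb0 <- spec$ventAxesMm[2]
  vx <- spec$ventOffsetMm[1]; vy <- spec$ventOffsetMm[2]
  for (k in seq_len(spec$nSlices)) {
    scale <- max(0, 1 - spec$sliceScaleStep * abs(k - spec$peakSlice))
    va <- va0 * scale; vb <- vb0 * scale
    sl <- matrix(spec$bgIntensity, nx, ny)
    sl[inBrain] <- spec$brainIntensity
    plexusArea <- 0
    if (va > 0 && vb > 0) {
      inV1 <- ((X + vx) / va)^2 + ((Y - vy) / vb)^2 <= 1
      inV2 <- ((X - vx) / va)^2 + ((Y - vy) / vb)^2 <= 1
      sl[inV1 | inV2] <- spec$ventIntensity
      if (spec$plexusRadiusMm > 0) {
        pr <- spec$plexusRadiusMm
        pcx <- -vx + spec$plexusOffsetMm[1]
        pcy <- vy + spec$plexusOffsetMm[2]
        fits <- (spec$plexusOffsetMm[1] / max(va - pr, 1e-9))^2 +
          (spec$plexusOffsetMm[2] / max(vb - pr, 1e-9))^2 <= 1 &&
          pr < min(va, vb)
        if (fits) {
          inP <- (X - pcx)^2 + (Y - pcy)^2 <= pr^2
          sl[inP] <- spec$plexusIntensity
          plexusArea <- pi * pr^2
        }
      }
    }
    vol[, , k] <- sl
    ventArea <- 2 * pi * va * vb - plexusArea
    brainArea <- pi * a * b - 2 * pi * va * vb
    perSlice[k, 2:5] <- c(scale, ventArea, brainArea, ventArea / brainArea)
  }
  if (spec$noiseSd > 0)
    vol <- vol + array(rnorm(length(vol), 0, spec$noiseSd), dim = dim(vol))

  # rough ROI polygons in 0-based pixel coordinates (shared by all slices)
  toPx <- function(xmm, ymm) cbind((xmm + cx) / h, (ymm + cy) / h)
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  brainRoi <- toPx(1.04 * a * cos(ang) + 2 * sign(cos(ang)),
                   1.04 * b * sin(ang) + 2 * sign(sin(ang)))
  vm <- 3
  ventRoi <- toPx(c(-vx - va0 - vm, vx + va0 + vm, vx + va0 + vm,
                    -vx - va0 - vm),
                  c(vy - vb0 - vm, vy - vb0 - vm, vy + vb0 + vm,
                    vy + vb0 + vm))
  # gradient line crossing the second ventricle's lateral edge: its
  # max-gradient threshold sits at the ventricle/brain ramp midpoint
  thrLine <- toPx(c(vx, vx + va0 + 3), c(vy, vy))
  gt <- list(kind = "brain", perSlice = perSlice, peakSlice = spec$peakSlice,
             rois = list(ventricle = ventRoi, brain = brainRoi,
                         thresholdLine = thrLine),
             plexusRadiusMm = spec$plexusRadiusMm, seed = spec$seed)
  new("Volume3D", data = vol,
      spacingMm = c(h, h, spec$sliceThicknessMm), groundTruth = gt)
}

# Wrap velocities into (-venc, +venc] by modular arithmetic of period
# 2*venc (single-wrap aliasing model).
wrapVelocity <- function(v, vencCms) {
  v - 2 * vencCms * ceiling((v - vencCms) / (2 * vencCms))
}

#' Specification of a cine phase-contrast phantom
#'
#' A circular lumen whose velocity field is a parabolic (Poiseuille) profile
#' scaled by a mean-velocity waveform over one cardiac cycle, embedded in
#' static tissue. A constant background phase offset can be injected, values
#' can be wrapped (aliased) into the VENC window, and Gaussian velocity
#' noise added.
#'
#' @param nFrames frames per cycle (32 by default, matching one averaged
#'   cardiac cycle)
#' @param cycleMs cardiac period in ms
#' @param lumenRadiusMm lumen radius in mm
#' @param waveformAmpCms amplitude of the default sinusoidal mean-velocity
#'   waveform, cm/s
#' @param waveformFn optional mean-velocity function of time in ms returning
#'   cm/s (overrides the sinusoid)
#' @param vencCms velocity-encoding limit, cm/s
#' @param backgroundOffsetCms constant phase offset added everywhere, cm/s
#' @param alias logical; wrap stored velocities into (-VENC, +VENC]
#' @param noiseSdCms Gaussian velocity noise SD, cm/s
#' @param voxelSpacingMm in-plane pixel spacing, mm
#' @param fovMm in-plane field of view, mm
#' @param lumenMagnitude,tissueMagnitude magnitude-image intensities
#' @param seed RNG seed
#' @return a validated spec (list of class \code{cinePhantomSpec})
#' @export
cinePhantomSpec <- function(nFrames = 32L, cycleMs = 850,
                            lumenRadiusMm = 2, waveformAmpCms = 3,
                            waveformFn = NULL, vencCms = 10,
                            backgroundOffsetCms = 0, alias = FALSE,
                            noiseSdCms = 0, voxelSpacingMm = 0.5,
                            fovMm = 24, lumenMagnitude = 150,
                            tissueMagnitude = 100, seed = 1L) {
  stopifnot(nFrames >= 2, vencCms > 0, cycleMs > 0, lumenRadiusMm > 0,
            voxelSpacingMm > 0, noiseSdCms >= 0,
            2 * lumenRadiusMm < fovMm)
  if (is.null(waveformFn)) {
    A <- waveformAmpCms; Tms <- cycleMs
    waveformFn <- function(tMs) A * sin(2 * pi * tMs / Tms)
  }
  tq <- seq(0, cycleMs, length.out = 10001L)
  peak <- max(abs(2 * waveformFn(tq) + backgroundOffsetCms))
  if (alias && peak > 2 * vencCms)
    stop("peak velocity exceeds 2*VENC with alias=TRUE (double wrap)")
  structure(list(nFrames = as.integer(nFrames), cycleMs = cycleMs,
                 lumenRadiusMm = lumenRadiusMm, waveformFn = waveformFn,
                 vencCms = vencCms,
                 backgroundOffsetCms = backgroundOffsetCms, alias = alias,
                 noiseSdCms = noiseSdCms, voxelSpacingMm = voxelSpacingMm,
                 fovMm = fovMm, lumenMagnitude = lumenMagnitude,
                 tissueMagnitude = tissueMagnitude,
                 seed = as.integer(seed)),
            class = "cinePhantomSpec")
}

#' Generate a cine phase-contrast phantom series
#'
#' Velocity frames contain \code{v(r, t) = 2 vbar(t) (1 - (r/R)^2)} inside
#' the lumen (zero in static tissue), plus the background offset everywhere;
#' noise is added, then values are wrapped into \code{(-VENC, +VENC]} when
#' \code{alias} is set. Ground-truth directional stroke volumes come from a
#' fine quadrature of lumen area times the mean-velocity waveform.
#'
#' @param spec a \code{\link{cinePhantomSpec}}
#' @return a \code{CinePCSeries} with ground truth attached
#' @export
generateCineSeries <- function(spec) {
  stopifnot(inherits(spec, "cinePhantomSpec"))
  set.seed(spec$seed)
  h <- spec$voxelSpacingMm
  n <- 2L * ceiling(spec$fovMm / 2 / h) + 1L
  c0 <- (n - 1) / 2 * h
  xs <- (seq_len(n) - 1) * h - c0
  r2 <- outer(xs^2, xs^2, "+")
  R <- spec$lumenRadiusMm
  lumen <- r2 <= R^2
  shape <- ifelse(lumen, 2 * (1 - r2 / R^2), 0)

  tMs <- (seq_len(spec$nFrames) - 1) / spec$nFrames * spec$cycleMs
  vbar <- spec$waveformFn(tMs)
  vel <- array(0, dim = c(n, n, spec$nFrames))
  mag <- array(0, dim = c(n, n, spec$nFrames))
  magBase <- matrix(spec$tissueMagnitude, n, n)
  magBase[lumen] <- spec$lumenMagnitude
  for (k in seq_len(spec$nFrames)) {
    vel[, , k] <- shape * vbar[k] + spec$backgroundOffsetCms
    mag[, , k] <- magBase
  }
  trueVel <- vel
  if (spec$noiseSdCms > 0) {
    vel <- vel + array(rnorm(length(vel), 0, spec$noiseSdCms), dim = dim(vel))
    mag <- pmax(mag + array(rnorm(length(mag), 0, spec$noiseSdCms * 10),
                            dim = dim(mag)), 0)
  }
  if (spec$alias) vel <- wrapVelocity(vel, spec$vencCms)

  # ground-truth stroke volumes: Q(t) = S * vbar(t), S = analytic lumen area
  S <- pi * R^2
  tq <- seq(0, spec$cycleMs, length.out = 100001L)
  Q <- S * spec$waveformFn(tq) * 10          # cm/s -> mm/s
  dt <- diff(tq) / 1000                      # ms -> s
  trapzPart <- function(y) sum(dt * (head(y, -1) + tail(y, -1)) / 2)
  svPos <- trapzPart(pmax(Q, 0))
  svNeg <- abs(trapzPart(pmin(Q, 0)))
  gt <- list(kind = "cine", lumenMask = lumen, lumenAreaMm2 = S,
             vbarCms = vbar, trueVelocityCms = trueVel,
             svPosMm3 = svPos, svNegMm3 = svNeg,
             svMm3 = (svPos + svNeg) / 2,
             backgroundOffsetCms = spec$backgroundOffsetCms,
             seed = spec$seed)
  new("CinePCSeries", magnitude = mag, velocityCms = vel,
      vencCms = spec$vencCms, cycleMs = spec$cycleMs,
      pixelAreaMm2 = h * h, spacingMm = c(h, h),
      positiveDirection = "caudo-cranial", groundTruth = gt)
}

# Default per-sex parameter scales for the cohort generator (mean, sd),
# chosen to match the magnitudes of a healthy-adult cohort.
.cohortDefaults <- function() {
  list(
    male = list(age_years = c(26.2, 4.3), area_vent_mm2 = c(5.8, 1.7),
                area_brain_mm2 = c(151, 10), effective_length_mm = c(16.6, 2.8),
                d_min_mm = c(1.3, 0.2), d_mean_mm = c(2.0, 0.2),
                resistance = c(62, 38), cycle_ms = c(862, 151),
                sv_aq_mm3 = c(41, 18), sv_cv_mm3 = c(595, 161)),
    female = list(age_years = c(24.2, 3.3), area_vent_mm2 = c(7.2, 2.2),
                  area_brain_mm2 = c(140, 9), effective_length_mm = c(14.2, 2.5),
                  d_min_mm = c(1.2, 0.2), d_mean_mm = c(1.8, 0.3),
                  resistance = c(82, 45), cycle_ms = c(788, 112),
                  sv_aq_mm3 = c(30, 13), sv_cv_mm3 = c(600, 127)))
}

#' Specification of a synthetic cohort
#'
#' Per-sex means and SDs for each measured parameter (defaults at the scale
#' of a healthy-adult cohort), optional correlation targets between
#' parameter pairs, and outlier injections appended as extra subjects.
#'
#' @param nPerGroup subjects per sex group (>= 3)
#' @param paramsBySex list with elements \code{male} and \code{female}, each
#'   a named list of \code{c(mean, sd)} pairs
#' @param corrPairs list of \code{list(a, b, rho)} correlation targets
#' @param outliers list of \code{list(param, value)} injections
#' @param seed RNG seed
#' @return a validated spec (list of class \code{cohortSpec})
#' @export
cohortSpec <- function(nPerGroup = 17L, paramsBySex = .cohortDefaults(),
                       corrPairs = list(
                         list("resistance", "sv_aq_mm3", -0.5),
                         list("sv_aq_mm3", "sv_cv_mm3", 0.4),
                         list("sv_aq_mm3", "cycle_ms", 0.4),
                         list("d_min_mm", "d_mean_mm", 0.6),
                         list("resistance", "d_min_mm", -0.6)),
                       outliers = list(), seed = 1L) {
  stopifnot(nPerGroup >= 3)
  for (sx in c("male", "female")) {
    ps <- paramsBySex[[sx]]
    if (is.null(ps)) stop("paramsBySex needs 'male' and 'female'")
    sds <- vapply(ps, function(p) p[2], numeric(1))
    if (any(sds < 0)) stop("SDs must be >= 0")
  }
  structure(list(nPerGroup = as.integer(nPerGroup),
                 paramsBySex = paramsBySex, corrPairs = corrPairs,
                 outliers = outliers, seed = as.integer(seed)),
            class = "cohortSpec")
}

#' Generate a synthetic cohort table
#'
#' Draws per-subject parameters from sex-specific multivariate normal
#' distributions (correlation targets honoured via a Gaussian copula on the
#' listed pairs), derives the ratio parameters from their components
#' (\code{ratio_area = area_vent/area_brain * 100},
#' \code{ratio_sv = sv_aq/sv_cv * 100}, both in percent), and appends any
#' injected outlier subjects.
#'
#' @param spec a \code{\link{cohortSpec}}
#' @return a data.frame with one row per subject
#' @export
generateCohortTable <- function(spec) {
  stopifnot(inherits(spec, "cohortSpec"))
  set.seed(spec$seed)
  vars <- names(spec$paramsBySex$male)
  p <- length(vars)
  Rho <- diag(p); dimnames(Rho) <- list(vars, vars)
  for (cp in spec$corrPairs) {
    a <- cp[[1]]; b <- cp[[2]]
    if (a %in% vars && b %in% vars) {
      Rho[a, b] <- Rho[b, a] <- cp[[3]]
    }
  }
  ev <- eigen(Rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-6) {  # shrink toward identity until positive definite
    lam <- (1e-6 - min(ev)) / (1 - min(ev))
    Rho <- (1 - lam) * Rho + lam * diag(p)
  }

  drawGroup <- function(sx, n) {
    ps <- spec$paramsBySex[[sx]]
    mu <- vapply(ps, function(x) x[1], numeric(1))
    sdv <- vapply(ps, function(x) x[2], numeric(1))
    Sig <- Rho * tcrossprod(sdv)
    X <- MASS::mvrnorm(n, mu = mu, Sigma = Sig)
    X <- as.data.frame(matrix(X, nrow = n, byrow = n == 1L))
    names(X) <- vars
    # keep physically positive quantities away from zero
    for (v in setdiff(vars, "age_years"))
      X[[v]] <- pmax(X[[v]], 0.05 * mu[[v]])
    X
  }
  male <- drawGroup("male", spec$nPerGroup)
  female <- drawGroup("female", spec$nPerGroup)
  tab <- rbind(cbind(sex = "M", male), cbind(sex = "F", female))

  finish <- function(tab) {
    tab$ratio_area <- tab$area_vent_mm2 / tab$area_brain_mm2 * 100
    tab$ratio_sv <- tab$sv_aq_mm3 / tab$sv_cv_mm3 * 100
    tab$user_length_mm <- tab$effective_length_mm +
      pmax(rnorm(nrow(tab), 3, 1), 0.5)
    tab
  }
  tab <- finish(tab)

  for (ol in spec$outliers) {
    sx <- if (nrow(tab) %% 2 == 0) "male" else "female"
    row <- finish(cbind(sex = toupper(substr(sx, 1, 1)), drawGroup(sx, 1)))
    par <- ol[[1]]; val <- ol[[2]]
    if (par == "ratio_sv") {
      row$sv_aq_mm3 <- val / 100 * row$sv_cv_mm3
      row$ratio_sv <- val
    } else if (par == "ratio_area") {
      row$area_vent_mm2 <- val / 100 * row$area_brain_mm2
      row$ratio_area <- val
    } else row[[par]] <- val
    tab <- rbind(tab, row)
  }
  tab <- cbind(id = sprintf("S%02d", seq_len(nrow(tab))), tab)
  rownames(tab) <- NULL
  tab
}
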