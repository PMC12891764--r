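# Aqueductal hydraulic resistance: MIP projection of the morphological
# volume, gradient-guided binarization at the narrowest point, skeleton
# centerline between user landmarks, equal-arc-length microchannel
# decomposition, per-segment Poiseuille resistance
# R_i = 128 mu L_i / (pi D_i^4), and the 95% cumulative-resistance endpoint
# that standardizes the distal end of the aqueduct.

#' Parameters of the resistance model
#'
#' @param muMPaS dynamic viscosity in mPa s (default 0.71, water at 36 C)
#' @param nSegments number of microchannel segments (default 100)
#' @param endpointFraction cumulative-resistance cutoff defining the
#'   effective endpoint (default 0.95)
#' @param targetSpacingMm in-plane interpolation spacing for the projection
#'   image in mm (default 0.03)
#' @return a validated list of class \code{resistanceParams}
#' @export
resistanceParams <- function(muMPaS = 0.71, nSegments = 100L,
                             endpointFraction = 0.95,
                             targetSpacingMm = 0.03) {
  stopifnot(muMPaS > 0, nSegments >= 2, endpointFraction > 0,
            endpointFraction <= 1, targetSpacingMm > 0)
  structure(list(muMPaS = muMPaS, nSegments = as.integer(nSegments),
                 endpointFraction = endpointFraction,
                 targetSpacingMm = targetSpacingMm),
            class = "resistanceParams")
}

#' Maximum intensity projection across a slab
#'
#' @param volume a \code{Volume3D}
#' @param slabRange slice index range \code{c(from, to)} along the third
#'   axis (default: all slices)
#' @return a 2D image (per-pixel maximum across the slab)
#' @export
mipProject <- function(volume, slabRange = NULL) {
  stopifnot(is(volume, "Volume3D"))
  dat <- volData(volume)
  nz <- dim(dat)[3]
  if (is.null(slabRange)) slabRange <- c(1L, nz)
  slabRange <- as.integer(slabRange)
  if (slabRange[1] > slabRange[2] || slabRange[1] < 1 || slabRange[2] > nz)
    stop("empty or out-of-range slab")
  proj <- apply(dat[, , slabRange[1]:slabRange[2], drop = FALSE],
                c(1, 2), max)
  image2d(proj, voxelSpacing(volume)[1:2])
}

#' Binarize the aqueduct projection
#'
#' Interpolates the projection to the analysis grid, derives the threshold
#' from the maximum intensity gradient along a line drawn across the
#' narrowest point of the aqueduct, thresholds the image, and keeps the
#' connected bright component containing the line midpoint.
#'
#' @param img 2D projection image
#' @param narrowestLine 2 x 2 matrix: line endpoints in 0-based pixel
#'   coordinates of \code{img}
#' @param targetSpacingMm interpolation spacing (default 0.03 mm)
#' @return logical lumen mask (a 2D image on the interpolated grid) with
#'   attributes \code{threshold} and \code{linePx} (the rescaled line)
#' @export
binarizeAqueduct <- function(img, narrowestLine, targetSpacingMm = 0.03) {
  sp <- pixelSpacing(img)
  fine <- interpolateToResolution(img, targetSpacingMm)
  lineF <- cbind(narrowestLine[, 1] * sp[1] / targetSpacingMm,
                 narrowestLine[, 2] * sp[2] / targetSpacingMm)
  thr <- thresholdMaxGradient(fine, lineF)
  bright <- fine >= thr
  mid <- colMeans(lineF)
  mask <- componentContaining(bright, mid, maxSnapPx = max(dim(fine)) / 20)
  mask <- image2d(mask * 1 > 0, pixelSpacing(fine))
  attr(mask, "threshold") <- thr
  attr(mask, "linePx") <- lineF
  mask
}

#' Extract the aqueduct centerline
#'
#' Thins the lumen mask to its morphological skeleton (Zhang-Suen), finds
#' the shortest skeleton path between the projections of the supplied start
#' and end points onto the skeleton, attaches the supplied endpoints,
#' smooths with a 5-sample moving average, and resamples at uniform
#' arc-length steps of one pixel.
#'
#' @param mask logical lumen mask (2D image)
#' @param startPx,endPx 0-based pixel coordinates of the start (distal
#'   third ventricle) and end (anterior fourth ventricle) points; must lie
#'   on or within one pixel of the mask
#' @return a list of class \code{centerline}: \code{pointsMm} (n x 2),
#'   \code{arcLengthMm} (cumulative), \code{spacingMm}
#' @export
extractCenterline <- function(mask, startPx, endPx) {
  sp <- pixelSpacing(mask)
  if (sqrt(sum((startPx - endPx)^2)) < 1e-9)
    stop("start and end points coincide")
  checkOn <- function(p) {
    i <- round(p[1]) + 1; j <- round(p[2]) + 1
    nbr <- expand.grid(di = -1:1, dj = -1:1)
    any(vapply(seq_len(nrow(nbr)), function(k) {
      ii <- i + nbr$di[k]; jj <- j + nbr$dj[k]
      ii >= 1 && jj >= 1 && ii <= nrow(mask) && jj <= ncol(mask) &&
        mask[ii, jj]
    }, logical(1)))
  }
  if (!checkOn(startPx) || !checkOn(endPx))
    stop("start/end point not on (or within one pixel of) the mask")

  skel <- zhangSuenThin(mask)
  sk <- which(skel, arr.ind = TRUE)  # 1-based [x, y]
  if (nrow(sk) < 2) stop("skeleton degenerate")
  # 8-neighbour graph over skeleton pixels, edge weight = distance in mm
  key <- (sk[, 1] - 1) + (sk[, 2] - 1) * nrow(mask)
  idx <- integer(nrow(mask) * ncol(mask)); idx[key + 1] <- seq_len(nrow(sk))
  edges <- NULL; wts <- NULL
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    ni <- sk[, 1] + d[1]; nj <- sk[, 2] + d[2]
    ok <- ni >= 1 & ni <= nrow(mask) & nj >= 1 & nj <= ncol(mask)
    nk <- ifelse(ok, idx[(ni - 1) + (nj - 1) * nrow(mask) + 1], 0L)
    sel <- ok & nk > 0
    if (any(sel)) {
      edges <- rbind(edges, cbind(which(sel), nk[sel]))
      wts <- c(wts, rep(sqrt(sum((d * sp)^2)), sum(sel)))
    }
  }
  if (is.null(edges)) stop("skeleton has no connected pixels")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- wts
  nearSk <- function(p) {
    which.min((sk[, 1] - 1 - p[1])^2 + (sk[, 2] - 1 - p[2])^2)
  }
  a <- nearSk(startPx); b <- nearSk(endPx)
  pathRes <- suppressWarnings(
    igraph::shortest_paths(g, from = a, to = b, output = "vpath"))
  vp <- pathRes$vpath[[1]]
  if (length(vp) == 0 && a != b)
    stop("mask is disconnected between the supplied start and end points")
  pPx <- sk[as.integer(vp), , drop = FALSE] - 1  # 0-based
  pts <- rbind(startPx, pPx, endPx)
  ptsMm <- cbind(pts[, 1] * sp[1], pts[, 2] * sp[2])
  sm <- smoothPolyline(ptsMm, 5L)
  sm[1, ] <- ptsMm[1, ]; sm[nrow(sm), ] <- ptsMm[nrow(ptsMm), ]
  total <- polylineLength(sm)
  nOut <- max(ceiling(total / min(sp)) + 1L, 11L)
  rs <- resamplePolyline(sm, nOut)
  structure(list(pointsMm = rs,
                 arcLengthMm = c(0, cumsum(sqrt(rowSums(diff(rs)^2)))),
                 spacingMm = sp),
            class = "centerline")
}

# First 0.5-crossing of the bilinearly sampled mask along a ray from
# `origin` (mm) in direction `dir` (unit, mm); returns distance in mm.
.chordHalf <- function(mask, originMm, dirMm, stepMm, maxMm) {
  sp <- pixelSpacing(mask)
  nStep <- ceiling(maxMm / stepMm)
  dist <- (0:nStep) * stepMm
  px <- cbind((originMm[1] + dist * dirMm[1]) / sp[1],
              (originMm[2] + dist * dirMm[2]) / sp[2])
  v <- sampleBilinear(mask * 1, px)
  below <- which(v < 0.5)
  if (length(below) == 0) return(maxMm)
  j <- below[1]
  if (j == 1) return(0)
  dist[j - 1] + (v[j - 1] - 0.5) / (v[j - 1] - v[j]) * stepMm
}

#' Decompose the aqueduct into microchannel segments
#'
#' Splits the centerline into \code{nSegments} equal-arc-length segments
#' and measures the local diameter D_i at each segment midpoint as the full
#' chord of the lumen mask along the normal to the centerline (sub-pixel
#' localization of the mask boundary by linear interpolation).
#'
#' @param centerline a \code{centerline} from \code{\link{extractCenterline}}
#' @param mask logical lumen mask the centerline lies in
#' @param params a \code{\link{resistanceParams}}
#' @return an \code{AqueductProfile} with lengths and diameters filled
#'   (resistances NA until \code{\link{poiseuilleResistance}})
#' @export
measureMicrochannels <- function(centerline, mask,
                                 params = resistanceParams()) {
  stopifnot(inherits(centerline, "centerline"),
            inherits(params, "resistanceParams"))
  n <- params$nSegments
  sp <- pixelSpacing(mask)
  pts <- resamplePolyline(centerline$pointsMm, n + 1L)
  segVec <- diff(pts)
  segLen <- sqrt(rowSums(segVec^2))
  total <- sum(segLen)
  mid <- (pts[-1, , drop = FALSE] + pts[-(n + 1), , drop = FALSE]) / 2
  tangent <- segVec / segLen
  normal <- cbind(-tangent[, 2], tangent[, 1])
  stepMm <- min(sp) / 3
  maxMm <- sqrt(sum((dim(mask) * sp)^2))
  D <- numeric(n)
  for (i in seq_len(n)) {
    dPlus <- .chordHalf(mask, mid[i, ], normal[i, ], stepMm, maxMm)
    dMinus <- .chordHalf(mask, mid[i, ], -normal[i, ], stepMm, maxMm)
    D[i] <- dPlus + dMinus
    if (D[i] <= 0)
      stop(sprintf("segment %d has zero diameter (midpoint off the mask)", i))
  }
  mc <- data.frame(i = seq_len(n), lengthMm = segLen, diameterMm = D,
                   resistance = NA_real_, cumResistance = NA_real_)
  new("AqueductProfile", microchannels = mc, centerlineMm = pts,
      userLengthMm = total, endpointIndex = NA_integer_,
      effectiveLengthMm = NA_real_, totalResistance = NA_real_,
      effectiveResistance = NA_real_, dMeanMm = NA_real_, dMinMm = NA_real_,
      params = unclass(params))
}

#' Segmental Poiseuille resistance
#'
#' Fills each microchannel's resistance
#' \code{R_i = 128 * mu * L_i / (pi * D_i^4)} (mPa s/mm^3 with L, D in mm
#' and mu in mPa s) and the cumulative-resistance curve.
#'
#' @param profile an \code{AqueductProfile}
#' @param params optional \code{\link{resistanceParams}} override
#' @return the profile with resistances and \code{totalResistance} filled
#' @export
poiseuilleResistance <- function(profile, params = NULL) {
  stopifnot(is(profile, "AqueductProfile"))
  p <- if (is.null(params)) profile@params else unclass(params)
  mc <- profile@microchannels
  stopifnot(all(mc$diameterMm > 0))
  mc$resistance <- 128 * p$muMPaS * mc$lengthMm / (pi * mc$diameterMm^4)
  mc$cumResistance <- cumsum(mc$resistance)
  profile@microchannels <- mc
  profile@totalResistance <- mc$cumResistance[nrow(mc)]
  profile@params <- p
  profile
}

#' Effective endpoint at the cumulative-resistance cutoff
#'
#' Sets the endpoint at the first segment whose cumulative resistance
#' reaches \code{endpointFraction} (default 95%) of the total, yielding the
#' effective length, the effective resistance (cumulative at the endpoint),
#' and the mean/minimum diameter over the effective length. This
#' standardizes the distal end against the wide, low-resistance distal
#' segment.
#'
#' @param profile an \code{AqueductProfile} with resistances filled
#' @param params optional \code{\link{resistanceParams}} override
#' @return the completed profile
#' @export
effectiveEndpoint <- function(profile, params = NULL) {
  stopifnot(is(profile, "AqueductProfile"))
  p <- if (is.null(params)) profile@params else unclass(params)
  mc <- profile@microchannels
  if (anyNA(mc$cumResistance))
    stop("cumulative resistance not computed; run poiseuilleResistance()")
  cutoff <- p$endpointFraction * profile@totalResistance
  idx <- which(mc$cumResistance >= cutoff - 1e-12)[1]
  profile@endpointIndex <- as.integer(idx)
  profile@effectiveLengthMm <- sum(mc$lengthMm[seq_len(idx)])
  profile@effectiveResistance <- mc$cumResistance[idx]
  profile@dMeanMm <- mean(mc$diameterMm[seq_len(idx)])
  profile@dMinMm <- min(mc$diameterMm[seq_len(idx)])
  profile@params <- p
  profile
}

#' Summary record of an aqueduct profile
#'
#' @param profile a completed \code{AqueductProfile}
#' @return one-row data.frame: effective resistance (reported as the
#'   aqueductal resistance), user-defined length, effective length, mean
#'   and minimum diameter
#' @export
summarizeAqueduct <- function(profile) {
  stopifnot(is(profile, "AqueductProfile"),
            !is.na(profile@endpointIndex))
  data.frame(resistance_mPa_s_mm3 = profile@effectiveResistance,
             user_length_mm = profile@userLengthMm,
             effective_length_mm = profile@effectiveLengthMm,
             d_mean_mm = profile@dMeanMm,
             d_min_mm = profile@dMinMm)
}

#' Full aqueduct resistance pipeline on a morphological volume
#'
#' MIP projection, interpolation + gradient-guided binarization, skeleton
#' centerline between the supplied landmarks, microchannel decomposition,
#' Poiseuille resistance, and endpoint standardization.
#'
#' @param volume a \code{Volume3D} (BFFE-like)
#' @param landmarks list with \code{startPx}, \code{endPx} (0-based pixel
#'   coordinates of the projection at native spacing) and
#'   \code{narrowLinePx} (2 x 2 matrix)
#' @param params a \code{\link{resistanceParams}}
#' @param slabRange optional slab for the projection
#' @return a completed \code{AqueductProfile}
#' @export
analyzeAqueduct <- function(volume, landmarks, params = resistanceParams(),
                            slabRange = NULL) {
  proj <- mipProject(volume, slabRange)
  mask <- binarizeAqueduct(proj, landmarks$narrowLinePx,
                           params$targetSpacingMm)
  sp <- pixelSpacing(proj)
  fs <- pixelSpacing(mask)
  scalePt <- function(p) c(p[1] * sp[1] / fs[1], p[2] * sp[2] / fs[2])
  cl <- extractCenterline(mask, scalePt(landmarks$startPx),
                          scalePt(landmarks$endPx))
  prof <- measureMicrochannels(cl, mask, params)
  prof <- poiseuilleResistance(prof)
  effectiveEndpoint(prof)
}
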