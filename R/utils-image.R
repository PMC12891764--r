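# 2D image helpers shared by the morphometry and aqueduct modules.
#
# Conventions (documented in ?aqueflowConventions):
#   * a 2D image is a numeric matrix indexed [x, y] with a "spacingMm"
#     attribute (length-2, mm); pixel centers sit at (index - 1) * spacing
#   * points and polygons use 0-based pixel coordinates (x, y), so point
#     (0, 0) is the center of pixel [1, 1]

#' Package conventions
#'
#' 2D images are numeric matrices indexed \code{[x, y]} carrying a
#' \code{"spacingMm"} attribute (pixel spacing in mm); pixel centers lie at
#' \code{(index - 1) * spacing} mm. All point, line and polygon inputs use
#' 0-based pixel coordinates \code{(x, y)}. Polygon membership uses the
#' even-odd rule applied to pixel centers. Lengths and diameters are in mm,
#' viscosity in mPa s, hydraulic resistance in mPa s/mm^3, velocities in
#' cm/s, flow rates in mm^3/s, stroke volumes in mm^3.
#'
#' @name aqueflowConventions
NULL

#' Construct a 2D image
#'
#' @param mat numeric matrix indexed \code{[x, y]}
#' @param spacingMm pixel spacing in mm (scalar or length-2)
#' @return the matrix with a \code{"spacingMm"} attribute
#' @export
image2d <- function(mat, spacingMm) {
  stopifnot(is.matrix(mat), all(spacingMm > 0))
  if (length(spacingMm) == 1L) spacingMm <- rep(spacingMm, 2L)
  attr(mat, "spacingMm") <- as.numeric(spacingMm[1:2])
  mat
}

#' @rdname image2d
#' @param img a 2D image created by \code{image2d}
#' @export
pixelSpacing <- function(img) {
  sp <- attr(img, "spacingMm")
  if (is.null(sp)) stop("image has no spacingMm attribute; use image2d()")
  sp
}

# Bilinear sampling at 0-based pixel coordinates, clamped to the image border.
# xy: n x 2 matrix. Returns a numeric vector.
sampleBilinear <- function(img, xy) {
  nx <- nrow(img); ny <- ncol(img)
  x <- pmin(pmax(xy[, 1], 0), nx - 1)
  y <- pmin(pmax(xy[, 2], 0), ny - 1)
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  if (nx == 1L) x0 <- x * 0
  if (ny == 1L) y0 <- y * 0
  fx <- x - x0; fy <- y - y0
  i0 <- x0 + 1; j0 <- y0 + 1
  i1 <- pmin(i0 + 1, nx); j1 <- pmin(j0 + 1, ny)
  img[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    img[cbind(i1, j0)] * fx * (1 - fy) +
    img[cbind(i0, j1)] * (1 - fx) * fy +
    img[cbind(i1, j1)] * fx * fy
}

#' Bilinearly interpolate an image to a finer resolution
#'
#' Resamples a 2D image onto a grid with the requested pixel spacing using
#' bilinear interpolation. The physical extent (distance between first and
#' last pixel centers) is preserved to within one target pixel.
#'
#' @param img 2D image (see \code{\link{image2d}})
#' @param targetSpacingMm target pixel spacing in mm (scalar or length-2);
#'   must not exceed the source spacing
#' @return the interpolated 2D image
#' @export
interpolateToResolution <- function(img, targetSpacingMm) {
  sp <- pixelSpacing(img)
  if (length(targetSpacingMm) == 1L)
    targetSpacingMm <- rep(targetSpacingMm, 2L)
  if (any(targetSpacingMm > sp + 1e-12))
    stop("target spacing must be <= source spacing")
  if (any(sp / targetSpacingMm > 100))
    stop("upsampling factor > 100 rejected")
  extent <- (dim(img) - 1) * sp
  nNew <- floor(extent / targetSpacingMm + 1e-9) + 1
  gx <- (seq_len(nNew[1]) - 1) * targetSpacingMm[1] / sp[1]
  gy <- (seq_len(nNew[2]) - 1) * targetSpacingMm[2] / sp[2]
  xy <- cbind(rep(gx, times = nNew[2]), rep(gy, each = nNew[1]))
  out <- matrix(sampleBilinear(img, xy), nNew[1], nNew[2])
  image2d(out, targetSpacingMm)
}

#' Rasterize a polygon to a pixel mask
#'
#' A pixel belongs to the polygon if its center is inside under the even-odd
#' rule. Vertices are 0-based pixel coordinates \code{(x, y)}.
#'
#' @param dims image dimensions \code{c(nx, ny)}
#' @param polygon n x 2 matrix of vertices (at least 3)
#' @return logical matrix of dimension \code{dims}
#' @export
polygonMask <- function(dims, polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices")
  nx <- dims[1]; ny <- dims[2]
  px <- rep(seq_len(nx) - 1, times = ny)
  py <- rep(seq_len(ny) - 1, each = nx)
  inside <- rep(FALSE, nx * ny)
  n <- nrow(polygon)
  j <- n
  for (i in seq_len(n)) {
    xi <- polygon[i, 1]; yi <- polygon[i, 2]
    xj <- polygon[j, 1]; yj <- polygon[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nx, ny)
}

# Otsu threshold: maximizes between-class variance over a 256-bin histogram
# of the supplied intensities. Deterministic automatic fallback when no
# gradient line is available.
otsuThreshold <- function(values) {
  values <- values[is.finite(values)]
  r <- range(values)
  if (diff(r) == 0) stop("constant intensities: no threshold exists")
  nb <- 256L
  h <- tabulate(pmin(pmax(
    floor((values - r[1]) / diff(r) * nb) + 1L, 1L), nb), nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nb))
  muT <- mu[nb]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- -Inf
  k <- which.max(sigmaB)  # first maximum on ties
  r[1] + (k - 0.5) / nb * diff(r)
}

# Zhang-Suen thinning of a logical matrix (TRUE = foreground). Vectorized
# over the image; iterates the two sub-steps until no pixel changes.
zhangSuenThin <- function(mask) {
  img <- mask != 0
  nx <- nrow(img); ny <- ncol(img)
  pad <- function(m) {
    out <- matrix(FALSE, nx + 2, ny + 2)
    out[2:(nx + 1), 2:(ny + 1)] <- m
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- pad(img)
      # neighbours clockwise from north; image y grows downward in pixel
      # coordinates but the rule set is rotation-invariant
      P2 <- p[2:(nx + 1), 1:ny];         P3 <- p[3:(nx + 2), 1:ny]
      P4 <- p[3:(nx + 2), 2:(ny + 1)];   P5 <- p[3:(nx + 2), 3:(ny + 2)]
      P6 <- p[2:(nx + 1), 3:(ny + 2)];   P7 <- p[1:nx, 3:(ny + 2)]
      P8 <- p[1:nx, 2:(ny + 1)];         P9 <- p[1:nx, 1:ny]
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
        (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      if (step == 1L)
        cond <- !(P2 & P4 & P6) & !(P4 & P6 & P8)
      else
        cond <- !(P2 & P4 & P8) & !(P2 & P6 & P8)
      del <- img & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        img[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

# Connected component (8-connectivity) of a binary mask containing the given
# 0-based point; if the point is not on the mask, snap to the nearest
# foreground pixel within maxSnapPx. Errors when no component can be found.
componentContaining <- function(mask, pointXY, maxSnapPx = 2) {
  lab <- EBImage::bwlabel(mask != 0)
  i <- round(pointXY[1]) + 1; j <- round(pointXY[2]) + 1
  i <- min(max(i, 1), nrow(mask)); j <- min(max(j, 1), ncol(mask))
  id <- lab[i, j]
  if (id == 0) {
    fg <- which(mask != 0, arr.ind = TRUE)
    if (nrow(fg) == 0) stop("mask is empty")
    d2 <- (fg[, 1] - i)^2 + (fg[, 2] - j)^2
    k <- which.min(d2)
    if (d2[k] > maxSnapPx^2)
      stop("no connected component contains the supplied point")
    id <- lab[fg[k, 1], fg[k, 2]]
  }
  lab == id
}

# Moving-average smoothing of an n x 2 polyline with partial windows at the
# ends (window is the full width, odd).
smoothPolyline <- function(pts, window = 5L) {
  n <- nrow(pts)
  half <- window %/% 2L
  out <- pts
  for (i in seq_len(n)) {
    a <- max(1L, i - half); b <- min(n, i + half)
    out[i, ] <- colMeans(pts[a:b, , drop = FALSE])
  }
  out
}

# Resample an n x 2 polyline at m points uniform in arc length.
resamplePolyline <- function(pts, m) {
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  keep <- c(TRUE, seg > 0)  # drop duplicated points
  s <- s[keep]; pts <- pts[keep, , drop = FALSE]
  if (length(s) < 2L) stop("degenerate polyline")
  sNew <- seq(0, s[length(s)], length.out = m)
  cbind(approx(s, pts[, 1], xout = sNew)$y,
        approx(s, pts[, 2], xout = sNew)$y)
}

polylineLength <- function(pts) sum(sqrt(rowSums(diff(pts)^2)))
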