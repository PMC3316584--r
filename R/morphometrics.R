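# Second-moment anisotropy of cell shapes and energy fields; focus selection;
# log-normal summaries.

.sobelX <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1))

# 'same' 2D convolution with zero padding
.conv2same <- function(img, k) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- img
  out <- matrix(0, nr, nc)
  for (i in 1:3) for (j in 1:3)
    if (k[i, j] != 0)
      out <- out + k[i, j] * pad[i:(i + nr - 1), j:(j + nc - 1)]
  out
}

#' Sharpest z-slice by the Tenengrad focus measure
#'
#' Scores each z-slice by the Tenengrad measure -- the sum of squared Sobel
#' gradient magnitudes -- inside a region of interest and returns the slice
#' index maximizing it. Ties break toward the lowest z.
#'
#' @param stack an [ImageStack-class].
#' @param roi optional numeric(4) `(xmin, xmax, ymin, ymax)` in um; default is
#'   the whole field.
#' @return 1-based z-slice index.
#' @export
focusPlane <- function(stack, roi = NULL) {
  d <- dim(stack@voxels)
  ix <- seq_len(d[1]); iy <- seq_len(d[2])
  if (!is.null(roi)) {
    stopifnot(length(roi) == 4L)
    xs <- stack@origin[1] + (ix - 0.5) * stack@spacing[1]
    ys <- stack@origin[2] + (iy - 0.5) * stack@spacing[2]
    ix <- ix[xs >= roi[1] & xs <= roi[2]]
    iy <- iy[ys >= roi[3] & ys <= roi[4]]
    if (length(ix) == 0 || length(iy) == 0) stop("roi outside stack bounds")
  }
  score <- vapply(seq_len(d[3]), function(k) {
    sl <- stack@voxels[ix, iy, k, drop = TRUE]
    if (!is.matrix(sl)) sl <- matrix(sl, length(ix), length(iy))
    gx <- .conv2same(sl, .sobelX)
    gy <- .conv2same(sl, t(.sobelX))
    sum(gx^2 + gy^2)
  }, numeric(1))
  which.max(score)   # which.max returns the first (lowest z) maximum
}

# even-odd rule point-in-polygon, vectorized over points
.inPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

.anisotropyFromMoments <- function(S, centroid) {
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev, decreasing = TRUE)
  if (ev[length(ev)] <= 0) stop("degenerate second-moment tensor")
  new("AnisotropyResult", tensor = S, eigenvalues = ev,
      index = ev[1] / ev[length(ev)], centroid = as.numeric(centroid))
}

#' Cell-shape anisotropy from a 2D contour
#'
#' Rasterizes a closed polygon (a manually outlined cell) to a binary mask at
#' the given pixel size, computes the centered 2x2 second-moment matrix over
#' the mask pixels, and returns the ratio of the maximum to the minimum
#' eigenvalue. A circular cell scores 1; elongated, spindle-like cells score
#' higher. The index is invariant under rotation, translation, and uniform
#' scaling of the contour.
#'
#' @param contour v x 2 matrix of polygon vertices, um (closed implicitly).
#' @param rasterSpacing raster pixel size, um; the default matches the
#'   reference acquisition's lateral pixel size (0.645 um).
#' @return an [AnisotropyResult-class]
#' @examples
#' th <- seq(0, 2 * pi, length.out = 65)[-65]
#' circle <- cbind(20 * cos(th), 20 * sin(th))
#' anisotropyIndex(shapeAnisotropy(circle))  # ~1
#' @export
shapeAnisotropy <- function(contour, rasterSpacing = 0.645) {
  contour <- matrix(as.numeric(contour), ncol = 2)
  if (nrow(contour) < 3L) stop("polygon needs at least 3 vertices")
  rx <- range(contour[, 1]); ry <- range(contour[, 2])
  if (diff(rx) == 0 || diff(ry) == 0) stop("degenerate (zero-area) polygon")
  xs <- seq(rx[1] - rasterSpacing, rx[2] + rasterSpacing, by = rasterSpacing)
  ys <- seq(ry[1] - rasterSpacing, ry[2] + rasterSpacing, by = rasterSpacing)
  g <- expand.grid(x = xs, y = ys)
  inside <- .inPolygon(g$x, g$y, contour[, 1], contour[, 2])
  if (!any(inside)) stop("degenerate (zero-area) polygon at this raster")
  px <- g$x[inside]; py <- g$y[inside]
  cx <- mean(px); cy <- mean(py)
  S <- matrix(c(sum((px - cx)^2), sum((px - cx) * (py - cy)),
                sum((px - cx) * (py - cy)), sum((py - cy)^2)), 2, 2)
  .anisotropyFromMoments(S, c(cx, cy))
}

#' Weighted second-moment anisotropy of a 3D point set
#'
#' The moment computation behind [energyAnisotropy()]: points weighted by
#' non-negative weights, centered at the weighted centroid; the index is the
#' ratio of the largest to the smallest eigenvalue of the 3x3 second-moment
#' tensor (1 for an isotropic distribution).
#'
#' @param points n x 3 matrix, um.
#' @param weights non-negative weights (energy per point).
#' @return an [AnisotropyResult-class]
#' @export
pointAnisotropy <- function(points, weights) {
  points <- matrix(as.numeric(points), ncol = 3)
  weights <- pmax(as.numeric(weights), 0)
  if (sum(weights) <= 0) stop("total weight is zero")
  ctr <- colSums(points * weights) / sum(weights)
  X <- sweep(points, 2, ctr)
  S <- crossprod(X * sqrt(weights))
  .anisotropyFromMoments(S, ctr)
}

#' Anisotropy of the strain energy density distribution
#'
#' Second moments of the strain energy density around a cell: element
#' centroids are weighted by their (floored non-negative) energy density
#' times element volume, centered at the energy-weighted centroid, and the
#' 3x3 moment tensor's eigenvalue ratio lambda_max / lambda_min is returned.
#' An isotropically contracting cell scores 1.
#'
#' @param field a [StrainEnergyField-class] with positive total floored
#'   energy.
#' @return an [AnisotropyResult-class]
#' @export
energyAnisotropy <- function(field) {
  stopifnot(is(field, "StrainEnergyField"))
  w <- pmax(field@density, 0) * field@mesh@volumes
  if (sum(w) <= 0) stop("total floored energy is zero")
  pointAnisotropy(elementCentroids(field@mesh), w)
}

#' Geometric mean, geometric standard error and log-normal fit
#'
#' Summary statistics for positively skewed, log-normally distributed
#' quantities (per-cell strain energies and anisotropy indices): the
#' geometric mean `exp(mean(log(x)))`, the geometric standard error
#' `exp(se(log(x)))`, and the log-normal parameters (mean and SD of the
#' logs).
#'
#' @param values positive numeric vector, length >= 2.
#' @return list with `geometric_mean`, `geometric_se`, `meanlog`, `sdlog`,
#'   and `n`.
#' @examples
#' geometricSummary(c(1, 100))$geometric_mean  # 10
#' @export
geometricSummary <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("values must be positive and finite")
  lv <- log(values)
  list(geometric_mean = exp(mean(lv)),
       geometric_se = exp(sd(lv) / sqrt(length(lv))),
       meanlog = mean(lv), sdlog = sd(lv), n = length(lv))
}
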