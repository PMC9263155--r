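# Slice-wise minimum-volume (minimum-area in 2D) enclosing ellipse.
#
# Khachiyan's barycentric-coordinate-descent algorithm on the lifted dual
# weights. The ellipse is the set {p : t(p - c) A (p - c) <= 1}; minimizing
# its area corresponds to maximizing det(A). Center, radii and rotation are
# recovered from A by singular value decomposition (r_i = 1 / sqrt(sigma_i)).

#' Fit the minimum-area enclosing ellipse of 2D points
#'
#' Khachiyan iteration until the dual-weight update falls below `tolerance`
#' (deterministic; no randomness). The final shape matrix is rescaled so
#' every input point satisfies the quadratic form `<= 1` exactly, which
#' changes the area by at most O(tolerance). Degenerate inputs (< 3 points,
#' or all points collinear) return an [Ellipse2D-class] flagged "point" or
#' "segment" for the caller to handle.
#'
#' @param points n x 2 matrix of mm coordinates.
#' @param tolerance convergence tolerance on the weight update (default
#'   1e-4).
#' @param maxIter iteration cap (default 1000).
#' @return an [Ellipse2D-class].
#' @examples
#' e <- mveeFit(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
#' e@radii  # unit circle
#' @export
mveeFit <- function(points, tolerance = 1e-4, maxIter = 1000L) {
  P <- rbind(points)
  storage.mode(P) <- "double"
  P <- unique(P)
  n <- nrow(P)
  degenerate <- function(kind) {
    ctr <- colMeans(P)
    new("Ellipse2D", center = ctr, radii = c(0, 0), rotation = diag(2),
        shape = diag(2) * Inf, degenerate = kind)
  }
  if (n == 1L) return(degenerate("point"))
  ctr <- colMeans(P)
  if (n == 2L || qr(sweep(P, 2, ctr))$rank < 2L) return(degenerate("segment"))
  d <- 2L
  Q <- t(cbind(P, 1))                       # (d+1) x n lifted points
  u <- rep(1 / n, n)
  for (iter in seq_len(maxIter)) {
    X <- Q %*% (u * t(Q))                   # (d+1) x (d+1)
    M <- colSums(Q * solve(X, Q))           # Mahalanobis distances
    j <- which.max(M)
    step <- (M[j] - d - 1) / ((d + 1) * (M[j] - 1))
    if (step < 0) step <- 0
    uNew <- u * (1 - step)
    uNew[j] <- uNew[j] + step
    if (sqrt(sum((uNew - u)^2)) < tolerance) { u <- uNew; break }
    u <- uNew
  }
  c0 <- as.numeric(t(P) %*% u)
  S <- t(P) %*% (u * P) - tcrossprod(c0)
  A <- solve(S) / d
  # enclose exactly: scale so the farthest point sits on the boundary
  dev <- sweep(P, 2, c0)
  qf <- rowSums((dev %*% A) * dev)
  A <- A / max(qf)
  A <- (A + t(A)) / 2
  sv <- svd(A)
  radii <- 1 / sqrt(sv$d)
  new("Ellipse2D", center = c0, radii = radii, rotation = sv$u,
      shape = A, degenerate = "none")
}

#' Quadratic form of points against an ellipse
#'
#' `t(p - c) A (p - c)`; <= 1 means inside or on the ellipse.
#'
#' @param e an [Ellipse2D-class].
#' @param points n x 2 matrix.
#' @return numeric vector.
#' @export
ellipseQuadForm <- function(e, points) {
  dev <- sweep(rbind(points), 2, e@center)
  rowSums((dev %*% e@shape) * dev)
}

#' Rebuild the shape matrix from rotation and radii
#'
#' Inverse of the SVD decomposition used by [mveeFit()]:
#' `A = R diag(1/r^2) t(R)`.
#'
#' @param rotation orthonormal 2x2 matrix.
#' @param radii semi-axes (r1, r2).
#' @return symmetric 2x2 shape matrix.
#' @export
ellipseShapeMatrix <- function(rotation, radii) {
  rotation %*% diag(1 / radii^2) %*% t(rotation)
}

#' Rasterize an ellipse onto a pixel lattice
#'
#' A pixel is marked iff its center satisfies the quadratic form `<= 1`
#' (boundary inclusive; a 1e-9 slack makes the inclusion robust to
#' round-off for pixels exactly on the boundary). Degenerate ellipses yield
#' an empty mask.
#'
#' @param e an [Ellipse2D-class].
#' @param xCenters,yCenters world mm coordinates of the pixel centers.
#' @return binary matrix of dimensions length(xCenters) x length(yCenters).
#' @export
fillEllipse <- function(e, xCenters, yCenters) {
  out <- matrix(0, length(xCenters), length(yCenters))
  if (e@degenerate != "none") return(out)
  pts <- cbind(rep(xCenters, times = length(yCenters)),
               rep(yCenters, each = length(xCenters)))
  out[ellipseQuadForm(e, pts) <= 1 + 1e-9] <- 1
  out
}

# Gather in-plane world (x, y) coordinates of necrotic pixels from oriented
# binary mask slices, grouped by the grid z-level each pixel lands on.
# Returns list(points = list over z of matrices, halfPlane/rows metadata).
maskPointsByLevel <- function(masks, axis, grid) {
  d <- gridDim(grid)
  acc <- vector("list", d[3])
  for (s in masks) {
    idx <- which(s@pixels != 0, arr.ind = TRUE)
    if (!nrow(idx)) next
    w <- sliceToWorld(s, idx, axis)
    k <- round((w[, 3] - grid@origin[3]) / grid@spacing[3]) + 1
    ok <- k >= 1 & k <= d[3]
    if (!any(ok)) next
    w <- w[ok, , drop = FALSE]; k <- k[ok]
    for (kk in unique(k)) {
      sel <- k == kk
      acc[[kk]] <- rbind(acc[[kk]], w[sel, 1:2, drop = FALSE])
    }
  }
  acc
}

#' Slice-wise MVEE reconstruction of the necrosis volume
#'
#' For each axial grid level, gathers the in-plane coordinates of necrotic
#' pixels from all accepted oriented masks, fits the minimum-area enclosing
#' ellipse, and rasterizes it; levels with fewer than 3 points or a
#' degenerate (point/segment) fit yield empty slices. Incomplete angular
#' data is bridged by the enclosing ellipse, which models the idealized
#' concentric heat distribution around the applicator.
#'
#' @param masks list of binary [OrientedSlice-class] masks (outlier-filtered).
#' @param axis an [ApplicatorAxis-class].
#' @param grid target [VoxelGrid-class] geometry.
#' @param tolerance Khachiyan tolerance.
#' @return list(volume = binary VoxelGrid, ellipses = data.frame(z, cx, cy,
#'   r1, r2, angleDeg) of the fitted per-level parameters).
#' @export
mveeReconstruct <- function(masks, axis, grid, tolerance = 1e-4) {
  d <- gridDim(grid)
  axes <- gridAxes(grid)
  vals <- array(0, dim = d)
  levels <- maskPointsByLevel(masks, axis, grid)
  ell <- list()
  for (k in seq_len(d[3])) {
    pts <- levels[[k]]
    if (is.null(pts) || nrow(unique(pts)) < 3L) next
    e <- mveeFit(pts, tolerance)
    if (e@degenerate != "none") next
    vals[, , k] <- fillEllipse(e, axes$x, axes$y)
    ell[[length(ell) + 1L]] <- data.frame(
      z = axes$z[k], cx = e@center[1], cy = e@center[2],
      r1 = e@radii[1], r2 = e@radii[2],
      angleDeg = atan2(e@rotation[2, 1], e@rotation[1, 1]) * 180 / pi)
  }
  list(volume = withGridValues(grid, vals),
       ellipses = if (length(ell)) do.call(rbind, ell) else
         data.frame(z = numeric(), cx = numeric(), cy = numeric(),
                    r1 = numeric(), r2 = numeric(), angleDeg = numeric()))
}
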