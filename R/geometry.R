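# Coordinate conventions and slice <-> world mapping shared by all backends.
#
# World frame: right-handed, mm, voxel centers; applicator axis parallel to z.
# A slice at rotation angle theta contains the axis; its in-plane directions
# are e_u = (cos theta, sin theta, 0) and e_z = (0, 0, 1). The slice covers
# both half-planes theta (u >= 0) and theta + 180 (u < 0), so a fan of 8
# slices yields 16 angular half-plane samples spaced 22.5 deg.

#' Map slice pixels to world coordinates
#'
#' @param slice an [OrientedSlice-class].
#' @param pixel integer pair (i, j), or an n x 2 matrix of pixel indices
#'   (1-based; i along u, j along z).
#' @param axis an [ApplicatorAxis-class].
#' @return world mm coordinates: a length-3 vector, or an n x 3 matrix.
#' @examples
#' s <- orientedSlice(matrix(0, 21, 5), angle = 90)
#' a <- applicatorAxis(0, 0)
#' sliceToWorld(s, c(21, 3), a)  # u = +10 mm at 90 deg -> (0, 10, 0)
#' @export
sliceToWorld <- function(slice, pixel, axis) {
  p <- rbind(pixel)
  if (any(p[, 1] < 1 | p[, 1] > nrow(slice@pixels) |
          p[, 2] < 1 | p[, 2] > ncol(slice@pixels)))
    stop("pixel index out of slice bounds")
  u <- slice@origin[1] + (p[, 1] - 1) * slice@spacing[1]
  z <- slice@origin[2] + (p[, 2] - 1) * slice@spacing[2]
  th <- slice@angle * pi / 180
  w <- cbind(axis@center[1] + u * cos(th), axis@center[2] + u * sin(th), z)
  dimnames(w) <- NULL
  if (is.vector(pixel) && length(pixel) == 2L) w[1, ] else w
}

#' Map world points back to (fractional) slice pixel indices
#'
#' Inverse of [sliceToWorld()] for points lying on the slice plane; the
#' out-of-plane residual is returned so callers can check planarity.
#'
#' @inheritParams sliceToWorld
#' @param p world mm point (length 3) or n x 3 matrix.
#' @return list(pixel = n x 2 fractional indices, offPlane = signed mm
#'   distance from the slice plane).
#' @export
worldToSlice <- function(slice, p, axis) {
  p <- rbind(p)
  th <- slice@angle * pi / 180
  dx <- p[, 1] - axis@center[1]
  dy <- p[, 2] - axis@center[2]
  u <- dx * cos(th) + dy * sin(th)
  off <- -dx * sin(th) + dy * cos(th)
  i <- (u - slice@origin[1]) / slice@spacing[1] + 1
  j <- (p[, 3] - slice@origin[2]) / slice@spacing[2] + 1
  list(pixel = cbind(i, j), offPlane = off)
}

#' Convert world points to cylindrical coordinates about the applicator axis
#'
#' `r = sqrt((x - x_c)^2 + (y - y_c)^2)`; `theta` is the two-argument
#' arctangent of the in-plane offset, mapped to \[0, 360) degrees with
#' `theta = 0` along +x; points on the axis get `theta = 0` by convention;
#' z passes through unchanged.
#'
#' @param p world mm point (length 3 or n x 3 matrix); a 2-column input is
#'   treated as in-plane (x, y) with z = 0.
#' @param axis an [ApplicatorAxis-class].
#' @return data.frame(r, theta, z) with r in mm, theta in degrees.
#' @examples
#' toCylindrical(c(1, 0, 5), applicatorAxis(0, 0))  # r = 1, theta = 0
#' @export
toCylindrical <- function(p, axis) {
  p <- rbind(p)
  dimnames(p) <- NULL
  if (ncol(p) == 2L) p <- cbind(p, 0)
  dx <- p[, 1] - axis@center[1]
  dy <- p[, 2] - axis@center[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- ifelse(r < 1e-12, 0, atan2(dy, dx) * 180 / pi) %% 360
  data.frame(r = r, theta = theta, z = p[, 3])
}

#' Half-plane angles of a slice fan
#'
#' The 2 * n angular half-plane samples (degrees, sorted, in \[0, 360))
#' contributed by n slice orientations in \[0, 180).
#'
#' @param orientationAngles slice angles in degrees.
#' @return sorted numeric vector of half-plane angles.
#' @export
halfPlaneAngles <- function(orientationAngles) {
  sort(c(orientationAngles %% 360, (orientationAngles + 180) %% 360))
}

#' Uniform orientation angles for a fan of n slices
#'
#' @param nOrientations number of slice orientations.
#' @return angles `0, 180/n, ..., 180 (n-1)/n` degrees.
#' @export
orientationAngles <- function(nOrientations) {
  (seq_len(nOrientations) - 1) * 180 / nOrientations
}

#' Scatter a one-timestamp slice series into a sparse voxel grid
#'
#' Each slice's pixels are written into the nearest grid voxel on its plane
#' (nearest-neighbor); voxels not intersected by any slice plane stay `NA`
#' (absent). Intended for inspection and for resampling checks; the
#' reconstruction backends consume the slices directly.
#'
#' @param series [OrientedSliceSeries-class] restricted to one timestamp.
#' @param grid target [VoxelGrid-class] (geometry only; values ignored).
#' @param axis [ApplicatorAxis-class].
#' @return a VoxelGrid whose values are slice samples or NA where absent.
#' @export
resampleSlicesToGrid <- function(series, grid, axis) {
  ts <- unique(sliceTimestamps(series))
  if (length(ts) > 1L) stop("series must cover a single timestamp")
  d <- gridDim(grid)
  vals <- array(NA_real_, dim = d)
  for (s in series@slices) {
    if (abs(s@spacing[1] - grid@spacing[1]) > 1e-6 ||
        abs(s@spacing[1] - grid@spacing[2]) > 1e-6 ||
        abs(s@spacing[2] - grid@spacing[3]) > 1e-6)
      stop("slice spacing incompatible with grid spacing")
    np <- nrow(s@pixels) * ncol(s@pixels)
    idx <- cbind(rep(seq_len(nrow(s@pixels)), times = ncol(s@pixels)),
                 rep(seq_len(ncol(s@pixels)), each = nrow(s@pixels)))
    w <- sliceToWorld(s, idx, axis)
    vox <- round(sweep(sweep(w, 2, grid@origin), 2, grid@spacing, "/")) + 1
    ok <- vox[, 1] >= 1 & vox[, 1] <= d[1] & vox[, 2] >= 1 & vox[, 2] <= d[2] &
          vox[, 3] >= 1 & vox[, 3] <= d[3]
    vals[vox[ok, , drop = FALSE]] <- as.vector(s@pixels)[ok]
  }
  withGridValues(grid, vals)
}
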