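# Baseline method: reconstruct a volumetric temperature map by angular
# interpolation between adjacent slice half-planes, then threshold the
# volume. The per-voxel interpolation partners and weights depend only on
# the acquisition geometry, so they are precomputed once into a population
# map after the reference images are acquired and reused for every frame.

#' Build the angular-interpolation population map
#'
#' For every in-plane position, finds the two half-planes bracketing its
#' cylindrical angle (wrapping across 360 -> 0) and assigns convex weights
#' proportional to angular proximity: the nearer partner receives the larger
#' weight, `w_near = 1 - dtheta_near / dtheta_pair`, and `w1 + w2 = 1`.
#' A voxel lying exactly on a half-plane gives that plane full weight. The
#' inside-ROI indicator is 1 within the 60 x 60 mm cylinder around the
#' applicator. Because the axis is parallel to z, the map is 2D and shared
#' by all axial levels.
#'
#' @param grid target [VoxelGrid-class] geometry.
#' @param axis an [ApplicatorAxis-class].
#' @param angles half-plane angles in degrees (usually from
#'   [halfPlaneAngles()]; >= 2 distinct values).
#' @param roiSizeMm ROI cylinder diameter, mm.
#' @return list(partner1, partner2 = index matrices into `angles`;
#'   w1, w2 = weight matrices; r = in-plane radius matrix; roi = 0/1
#'   indicator matrix).
#' @export
buildPopulationMap <- function(grid, axis, angles, roiSizeMm = 60) {
  angles <- sort(unique(angles %% 360))
  if (length(angles) < 2L) stop("need >= 2 distinct half-plane angles")
  d <- gridDim(grid)
  axes <- gridAxes(grid)
  dx <- matrix(rep(axes$x - axis@center[1], times = d[2]), d[1], d[2])
  dy <- matrix(rep(axes$y - axis@center[2], each = d[1]), d[1], d[2])
  r <- sqrt(dx^2 + dy^2)
  theta <- ifelse(r < 1e-12, 0, atan2(dy, dx) * 180 / pi) %% 360
  # bracketing half-planes, wrapped: "left" is the last angle <= theta,
  # "right" the next one (cyclic)
  iLeft <- findInterval(theta, angles)            # 0 when theta < angles[1]
  nA <- length(angles)
  iLeft[iLeft == 0L] <- nA                        # wrap below the first angle
  iRight <- iLeft %% nA + 1L
  aLeft <- angles[iLeft]; aRight <- angles[iRight]
  dLeft <- (theta - aLeft) %% 360
  dPair <- (angles[iRight] - aLeft) %% 360
  dPair[dPair == 0] <- 360
  w1 <- 1 - dLeft / dPair                          # weight of the left plane
  exact <- dLeft < 1e-9
  w1[exact] <- 1
  roi <- (r <= roiSizeMm / 2) * 1
  list(partner1 = matrix(iLeft, d[1], d[2]), partner2 = matrix(iRight, d[1], d[2]),
       w1 = w1, w2 = 1 - w1, r = r, roi = roi, angles = angles)
}

# Radial temperature profiles per half-plane from one timestamp's slices:
# profiles[[h]] is a (radius index, z index) matrix sampled at du along u.
halfPlaneProfiles <- function(slices, angles, baseline) {
  prof <- vector("list", length(angles))
  for (s in slices) {
    u <- s@origin[1] + (seq_len(nrow(s@pixels)) - 1) * s@spacing[1]
    for (side in c(0, 180)) {
      a <- (s@angle + side) %% 360
      h <- which(abs(angles - a) < 1e-6)
      if (!length(h)) next
      sel <- if (side == 0) which(u >= -1e-9) else which(u <= 1e-9)
      sel <- sel[order(abs(u[sel]))]
      prof[[h]] <- list(values = s@pixels[sel, , drop = FALSE],
                        du = s@spacing[1],
                        z0 = s@origin[2], dz = s@spacing[2])
    }
  }
  prof
}

#' Interpolate a volumetric temperature map from slice half-planes
#'
#' Per voxel, samples each partner half-plane's temperature at the voxel's
#' (r, z) by nearest neighbor and blends with the population-map weights;
#' voxels outside the ROI, or with no partner data at all, are set to the
#' baseline temperature (with a warning in the latter case).
#'
#' @param pmap population map from [buildPopulationMap()].
#' @param slices list of temperature [OrientedSlice-class] objects at one
#'   timestamp (substitute an outlier orientation's last accepted slice
#'   upstream if desired).
#' @param grid target [VoxelGrid-class] geometry.
#' @param baseline degC assigned outside the ROI.
#' @return [VoxelGrid-class] of temperatures.
#' @export
interpolateVolume <- function(pmap, slices, grid, baseline = 20) {
  d <- gridDim(grid)
  axes <- gridAxes(grid)
  prof <- halfPlaneProfiles(slices, pmap$angles, baseline)
  have <- !vapply(prof, is.null, logical(1))
  if (!any(have)) {
    warning("no half-plane data; returning baseline volume")
    return(withGridValues(grid, array(baseline, dim = d)))
  }
  # per half-plane in-plane sample maps: temperature at (r, z-index)
  nIJ <- d[1] * d[2]
  vals <- array(baseline, dim = d)
  p1 <- as.vector(pmap$partner1); p2 <- as.vector(pmap$partner2)
  w1 <- as.vector(pmap$w1); w2 <- as.vector(pmap$w2)
  rv <- as.vector(pmap$r); roi <- as.vector(pmap$roi) != 0
  sampleHalf <- function(h, k) {
    pr <- prof[[h]]
    if (is.null(pr)) return(rep(NA_real_, nIJ))
    ri <- pmin(round(rv / pr$du) + 1L, nrow(pr$values))
    zi <- round((axes$z[k] - pr$z0) / pr$dz) + 1L
    if (zi < 1L || zi > ncol(pr$values)) return(rep(NA_real_, nIJ))
    pr$values[ri, zi]
  }
  for (k in seq_len(d[3])) {
    T1 <- rep(NA_real_, nIJ); T2 <- rep(NA_real_, nIJ)
    for (h in which(have)) {
      sel1 <- p1 == h; sel2 <- p2 == h
      if (any(sel1 | sel2)) {
        sh <- sampleHalf(h, k)
        T1[sel1] <- sh[sel1]
        T2[sel2] <- sh[sel2]
      }
    }
    Tk <- w1 * T1 + w2 * T2
    onlyT1 <- is.na(T2) & !is.na(T1); onlyT2 <- is.na(T1) & !is.na(T2)
    Tk[onlyT1] <- T1[onlyT1]
    Tk[onlyT2] <- T2[onlyT2]
    Tk[is.na(Tk)] <- baseline
    Tk[!roi] <- baseline
    vals[, , k] <- Tk
  }
  withGridValues(grid, vals)
}

#' Temperature-interpolation reconstruction of the necrosis volume
#'
#' Interpolates the volumetric temperature map, thresholds it at the
#' policy's single value (critical-temperature model), and keeps the
#' largest 26-connected component. The local and ground-truth policies are
#' unsupported: this method estimates necrosis on the reconstructed volume,
#' not on individual input slices.
#'
#' @param slices temperature [OrientedSlice-class] list at one timestamp.
#' @param tau threshold in degC (the global value or the resolved median).
#' @param grid target [VoxelGrid-class] geometry.
#' @param axis an [ApplicatorAxis-class].
#' @param roiSizeMm ROI cylinder diameter, mm.
#' @param baseline degC outside the ROI.
#' @return list(volume = binary VoxelGrid, temperature = VoxelGrid).
#' @export
interpReconstruct <- function(slices, tau, grid, axis, roiSizeMm = 60,
                              baseline = 20) {
  if (length(tau) != 1L || is.na(tau))
    stop("interpolation reconstruction requires a single threshold; ",
         "local and ground-truth policies are unsupported for this method")
  angles <- halfPlaneAngles(unique(vapply(slices, function(s) s@angle,
                                          numeric(1))))
  pmap <- buildPopulationMap(grid, axis, angles, roiSizeMm)
  temp <- interpolateVolume(pmap, slices, grid, baseline)
  mask <- (gridValues(temp) >= tau) * 1
  if (any(mask != 0)) mask <- largestComponent(mask)
  list(volume = withGridValues(grid, mask), temperature = temp)
}
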