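# Synthetic bio-protein phantom generator.
#
# The emulation targets the *level sets* of the treatment, not the physics:
# all reconstruction backends consume thresholded masks, so the temperature
# model is an analytic Gaussian-in-elliptic-radius profile whose iso-surface
# at the (angularly varying) coagulation threshold reproduces the analytic
# ground-truth ellipsoid exactly, up to voxelization. The heat-sink vessel is
# modelled as a cooled sheath (mask subtraction plus a smooth sigmoid dip of
# the temperature excess), not a solved convection term.

#' Construct a synthetic phantom specification
#'
#' Defaults emulate the acquisition conditions of a microwave ablation on an
#' ex vivo bio-protein phantom: a 256 x 256 x 256 mm volume at 1 mm voxels,
#' eight slice orientations of 256 x 256 px at 1.0 x 1.0 x 5.0 mm, a
#' 15-minute monotone ellipsoidal growth of the coagulation zone, room
#' baseline temperature (20 degC), 90 degC at the applicator, per-orientation
#' coagulation thresholds drawn from the 50-60 degC envelope of pH-driven
#' phantom inhomogeneity, 1 degC thermometry noise inside the 60 x 60 mm ROI
#' and stronger background noise outside it.
#'
#' @param gridShape,gridSpacing reconstruction/ground-truth grid geometry.
#' @param axisCenter world (x_c, y_c) of the applicator axis, mm.
#' @param semiAxesMax final ellipsoid semi-axes (in-plane a, axial c), mm.
#' @param centerZ ellipsoid center along the axis, mm.
#' @param tEnd treatment duration, s.
#' @param growthExponent semi-axes grow as (t/tEnd)^exponent (default 0.5,
#'   diffusive radius growth).
#' @param baselineTemp,peakTemp degC.
#' @param thresholds per-orientation coagulation thresholds in \[50, 60\]
#'   degC; NULL draws them uniformly from that envelope under `seed`.
#' @param nOrientations number of slice orientations.
#' @param sliceShape,sliceSpacing,sliceThickness slice geometry; NULL derives
#'   the shape from the grid.
#' @param noiseSd,bgNoiseSd degC noise inside / extra outside the ROI.
#' @param roiSizeMm region-of-interest edge, mm.
#' @param vessel NULL (no vessel) or a list overriding any of: center
#'   (x, z mm — the tube runs along y, perpendicular to the applicator
#'   axis, crossing the zone at that in-plane offset and height),
#'   outerDiameter (7 mm = 5 mm lumen + 1 mm wall each side),
#'   coolingRadius (5 mm), transitionWidth (1 mm ramp inside the cooling
#'   radius; the field is unmodified at and beyond it).
#' @param outlierSchedule data.frame(orientation, timestamp) of slices to
#'   corrupt (orientation is the 1-based index into the angle fan).
#' @param outlierNoiseFactor noise multiplier on corrupted slices.
#' @param seed integer; every random element of the phantom derives from it.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(gridShape = c(256L, 256L, 256L),
                        gridSpacing = c(1, 1, 1),
                        axisCenter = c(0, 0),
                        semiAxesMax = c(10, 20),
                        centerZ = 0,
                        tEnd = 900,
                        growthExponent = 0.5,
                        baselineTemp = 20,
                        peakTemp = 90,
                        thresholds = NULL,
                        nOrientations = 8L,
                        sliceShape = NULL,
                        sliceSpacing = c(1, 1),
                        sliceThickness = 5,
                        noiseSd = 1,
                        bgNoiseSd = 3,
                        roiSizeMm = 60,
                        vessel = NULL,
                        outlierSchedule = data.frame(orientation = integer(),
                                                     timestamp = numeric()),
                        outlierNoiseFactor = 200,
                        seed = 1L) {
  if (is.null(thresholds)) {
    set.seed(seed)
    thresholds <- stats::runif(nOrientations, 50, 60)
  }
  if (is.null(sliceShape))
    sliceShape <- c(gridShape[1], gridShape[3])
  v <- list(enabled = FALSE)
  if (!is.null(vessel)) {
    v <- utils::modifyList(
      list(enabled = TRUE, center = c(semiAxesMax[1] * 0.8, 0),
           outerDiameter = 7, wall = 1, coolingRadius = 5,
           transitionWidth = 1),
      vessel)
  }
  new("PhantomSpec",
      gridShape = as.integer(gridShape), gridSpacing = as.numeric(gridSpacing),
      axisCenter = as.numeric(axisCenter),
      semiAxesMax = as.numeric(semiAxesMax), centerZ = as.numeric(centerZ),
      tEnd = as.numeric(tEnd), growthExponent = as.numeric(growthExponent),
      baselineTemp = as.numeric(baselineTemp), peakTemp = as.numeric(peakTemp),
      thresholds = as.numeric(thresholds),
      nOrientations = as.integer(nOrientations),
      sliceShape = as.integer(sliceShape),
      sliceSpacing = as.numeric(sliceSpacing),
      sliceThickness = as.numeric(sliceThickness),
      noiseSd = as.numeric(noiseSd), bgNoiseSd = as.numeric(bgNoiseSd),
      roiSizeMm = as.numeric(roiSizeMm), vessel = v,
      outlierSchedule = outlierSchedule,
      outlierNoiseFactor = as.numeric(outlierNoiseFactor),
      seed = as.integer(seed))
}

#' @describeIn phantomSpec the reconstruction grid implied by the spec.
#' @param spec a [PhantomSpec-class].
#' @export
phantomGrid <- function(spec) {
  voxelGrid(0, spacing = spec@gridSpacing, shape = spec@gridShape)
}

#' @describeIn phantomSpec the applicator axis implied by the spec.
#' @export
phantomAxis <- function(spec) {
  applicatorAxis(spec@axisCenter[1], spec@axisCenter[2])
}

# Semi-axes (a, c) at time t; monotone non-decreasing, 0 at t = 0.
semiAxesAt <- function(spec, t) {
  f <- (min(max(t, 0), spec@tEnd) / spec@tEnd) ^ spec@growthExponent
  spec@semiAxesMax * f
}

# Coagulation threshold as a smooth periodic function of cylindrical angle
# (period 180 deg: both half-planes of a slice share its threshold).
thresholdAtAngle <- function(spec, thetaDeg) {
  n <- spec@nOrientations
  step <- 180 / n
  pos <- (thetaDeg %% 180) / step
  i0 <- floor(pos) %% n
  frac <- pos - floor(pos)
  tau <- spec@thresholds
  tau[i0 + 1] * (1 - frac) + tau[(i0 + 1) %% n + 1] * frac
}

# Noise-free temperature at arbitrary world points (n x 3 matrix).
temperatureAt <- function(spec, t, p) {
  p <- rbind(p)
  ax <- semiAxesAt(spec, t)
  base <- rep(spec@baselineTemp, nrow(p))
  if (ax[1] <= 0 || ax[2] <= 0) return(base)
  dx <- p[, 1] - spec@axisCenter[1]
  dy <- p[, 2] - spec@axisCenter[2]
  dz <- p[, 3] - spec@centerZ
  rho2 <- (dx^2 + dy^2) / ax[1]^2 + dz^2 / ax[2]^2
  theta <- ifelse(dx^2 + dy^2 < 1e-24, 0, atan2(dy, dx) * 180 / pi) %% 360
  tau <- thresholdAtAngle(spec, theta)
  k <- log((spec@peakTemp - spec@baselineTemp) / (tau - spec@baselineTemp))
  excess <- (spec@peakTemp - spec@baselineTemp) * exp(-k * rho2)
  if (isTRUE(spec@vessel$enabled)) {
    # tube along y at (x, z) = center: heat sink cools a sheath around it.
    # The ramp is 1 at and beyond the cooling radius so that thresholding
    # the field reproduces the ground truth (ellipsoid minus sheath) up to
    # voxelization; inside it falls linearly to 0 over transitionWidth.
    vd <- sqrt((p[, 1] - spec@vessel$center[1])^2 +
               (p[, 3] - spec@vessel$center[2])^2)
    s <- pmin(1, pmax(0, (vd - spec@vessel$coolingRadius +
                            spec@vessel$transitionWidth) /
                           spec@vessel$transitionWidth))
    excess <- excess * s
  }
  base + excess
}

#' Analytic ground-truth necrosis mask at time t
#'
#' The binary ellipsoid `rho <= 1` of the spec's semi-axes at `t`, centered
#' on the applicator axis, minus the cooled sheath around the vessel (all
#' voxels within the cooling radius of the vessel line) when a vessel is
#' present; reduced to its largest 26-connected component.
#'
#' @param spec a [PhantomSpec-class].
#' @param t time in s, within \[0, tEnd\].
#' @return binary [VoxelGrid-class].
#' @export
generateGroundTruth <- function(spec, t) {
  grid <- phantomGrid(spec)
  ax <- semiAxesAt(spec, t)
  d <- gridDim(grid)
  if (ax[1] <= 0 || ax[2] <= 0)
    return(withGridValues(grid, array(0, dim = d)))
  axes <- gridAxes(grid)
  dx2 <- (axes$x - spec@axisCenter[1])^2 / ax[1]^2
  dy2 <- (axes$y - spec@axisCenter[2])^2 / ax[1]^2
  dz2 <- (axes$z - spec@centerZ)^2 / ax[2]^2
  rho2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  mask <- (rho2 <= 1) * 1
  if (isTRUE(spec@vessel$enabled)) {
    vd2 <- outer((axes$x - spec@vessel$center[1])^2,
                 (axes$z - spec@vessel$center[2])^2, "+")  # (x, z) plane
    sheath <- vd2 <= spec@vessel$coolingRadius^2            # d1 x d3
    mask <- mask * !aperm(array(sheath, dim = d[c(1, 3, 2)]), c(1, 3, 2))
  }
  if (any(mask != 0)) mask <- largestComponent(mask)
  withGridValues(grid, mask)
}

#' Binary mask of the vessel tube on the phantom grid
#'
#' @inheritParams generateGroundTruth
#' @return binary [VoxelGrid-class] (all zero when no vessel is configured).
#' @export
vesselMask <- function(spec) {
  grid <- phantomGrid(spec)
  d <- gridDim(grid)
  if (!isTRUE(spec@vessel$enabled))
    return(withGridValues(grid, array(0, dim = d)))
  axes <- gridAxes(grid)
  vd2 <- outer((axes$x - spec@vessel$center[1])^2,
               (axes$z - spec@vessel$center[2])^2, "+")
  tube <- vd2 <= (spec@vessel$outerDiameter / 2)^2          # d1 x d3
  withGridValues(grid,
                 aperm(array(tube * 1, dim = d[c(1, 3, 2)]), c(1, 3, 2)))
}

phantomNoiseSeed <- function(spec, tag) {
  (spec@seed * 7919L + tag) %% .Machine$integer.max
}

#' Simulated volumetric temperature field at time t
#'
#' Smooth, radially decreasing about the applicator axis; thresholding the
#' noise-free field at the spec's angular threshold reproduces the ground
#' truth up to voxelization. Additive Gaussian noise of sd `noiseSd` is
#' applied deterministically under the spec seed.
#'
#' @inheritParams generateGroundTruth
#' @return [VoxelGrid-class] of temperatures in degC.
#' @export
simulateTemperatureField <- function(spec, t) {
  grid <- phantomGrid(spec)
  d <- gridDim(grid)
  axes <- gridAxes(grid)
  pts <- cbind(rep(axes$x, times = d[2] * d[3]),
               rep(rep(axes$y, each = d[1]), times = d[3]),
               rep(axes$z, each = d[1] * d[2]))
  temp <- array(temperatureAt(spec, t, pts), dim = d)
  if (spec@noiseSd > 0) {
    set.seed(phantomNoiseSeed(spec, as.integer(round(t)) %% 9973L))
    temp <- temp + array(stats::rnorm(prod(d), 0, spec@noiseSd), dim = d)
  }
  withGridValues(grid, temp)
}

phantomSliceGeometry <- function(spec) {
  nu <- spec@sliceShape[1]; nz <- spec@sliceShape[2]
  du <- spec@sliceSpacing[1]; dz <- spec@sliceSpacing[2]
  zOrigin <- spec@centerZ - (nz - 1) / 2 * dz
  list(nu = nu, nz = nz, du = du, dz = dz,
       u = (seq_len(nu) - 1 - floor(nu / 2)) * du,
       z = zOrigin + (seq_len(nz) - 1) * dz,
       origin = c(-floor(nu / 2) * du, zOrigin))
}

#' Sample the rotated temperature-slice series of a phantom
#'
#' For each timestamp and orientation angle the analytic temperature field
#' is sampled on the rotated plane at the slice's in-plane spacing. Noise of
#' sd `noiseSd` is added inside the ROI and `noiseSd + bgNoiseSd` outside it
#' (air background); slices listed in the spec's outlier schedule get their
#' noise sd multiplied by `outlierNoiseFactor`, which inflates their
#' thresholded area by far more than 80% relative to the previous frame.
#' Fully deterministic under the spec seed.
#'
#' @param spec a [PhantomSpec-class].
#' @param timestamps acquisition times, s.
#' @param nOrientations number of orientations (default from spec).
#' @return an [OrientedSliceSeries-class] of temperature slices (degC).
#' @export
sampleSliceSeries <- function(spec, timestamps,
                              nOrientations = spec@nOrientations) {
  stopifnot(nOrientations >= 2)
  geo <- phantomSliceGeometry(spec)
  angles <- orientationAngles(nOrientations)
  slices <- list()
  for (ti in seq_along(timestamps)) {
    t <- timestamps[ti]
    for (oi in seq_along(angles)) {
      th <- angles[oi] * pi / 180
      pts <- cbind(spec@axisCenter[1] + rep(geo$u, times = geo$nz) * cos(th),
                   spec@axisCenter[2] + rep(geo$u, times = geo$nz) * sin(th),
                   rep(geo$z, each = geo$nu))
      temp <- matrix(temperatureAt(spec, t, pts), geo$nu, geo$nz)
      sd <- spec@noiseSd
      corrupted <- any(spec@outlierSchedule$orientation == oi &
                       abs(spec@outlierSchedule$timestamp - t) < 1e-9)
      if (corrupted) sd <- sd * spec@outlierNoiseFactor
      if (sd > 0 || spec@bgNoiseSd > 0) {
        set.seed(phantomNoiseSeed(spec, 100003L * ti + 101L * oi))
        roi <- outer(abs(geo$u) <= spec@roiSizeMm / 2,
                     abs(geo$z - spec@centerZ) <= spec@roiSizeMm / 2, "&")
        n <- matrix(stats::rnorm(geo$nu * geo$nz), geo$nu, geo$nz)
        temp <- temp + n * ifelse(roi, sd, sd + spec@bgNoiseSd)
      }
      slices[[length(slices) + 1L]] <- orientedSlice(
        temp, angle = angles[oi],
        spacing = c(geo$du, geo$dz), thickness = spec@sliceThickness,
        timestamp = t, origin = geo$origin)
    }
  }
  orientedSliceSeries(slices, nOrientations)
}

#' Reslice a 3D ground-truth mask into the acquired slice fan
#'
#' Nearest-neighbor samples the binary volume on each rotated plane; the
#' result is the "perfect input" condition used by the ground-truth policy.
#'
#' @param gt binary [VoxelGrid-class].
#' @param axis an [ApplicatorAxis-class].
#' @param nOrientations number of orientations (default 8).
#' @param timestamp stamped on the output slices.
#' @param sliceSpacing in-plane mm pair (du, dz); defaults to the grid's.
#' @return an [OrientedSliceSeries-class] of binary slices.
#' @export
resliceGroundTruth <- function(gt, axis, nOrientations = 8L, timestamp = 0,
                               sliceSpacing = NULL) {
  if (!isBinaryGrid(gt)) stop("ground truth must be binary")
  d <- gridDim(gt)
  if (is.null(sliceSpacing))
    sliceSpacing <- c(gt@spacing[1], gt@spacing[3])
  nu <- d[1]; nz <- d[3]
  du <- sliceSpacing[1]; dz <- sliceSpacing[2]
  u <- (seq_len(nu) - 1 - floor(nu / 2)) * du
  z <- gt@origin[3] + (seq_len(nz) - 1) * dz
  angles <- orientationAngles(nOrientations)
  vals <- gridValues(gt)
  slices <- lapply(angles, function(a) {
    th <- a * pi / 180
    x <- axis@center[1] + u * cos(th)
    y <- axis@center[2] + u * sin(th)
    i <- round((x - gt@origin[1]) / gt@spacing[1]) + 1
    j <- round((y - gt@origin[2]) / gt@spacing[2]) + 1
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2]
    px <- matrix(0, nu, nz)
    if (any(ok))
      px[ok, ] <- vals[cbind(rep(i[ok], times = nz), rep(j[ok], times = nz),
                             rep(seq_len(nz), each = sum(ok)))]
    orientedSlice(px, angle = a, spacing = c(du, dz),
                  thickness = 5, timestamp = timestamp,
                  origin = c(-floor(nu / 2) * du, z[1]))
  })
  orientedSliceSeries(slices, nOrientations)
}

#' Synthetic phase pair consistent with the PRFS relation
#'
#' Builds (reference, heated) phase images whose wrapped difference encodes
#' the given temperature map under [prfsTemperature()]'s constants; used for
#' thermometry round-trip checks and for emitting phase-based phantom data.
#'
#' @param temp temperature map, degC (matrix).
#' @param k constants from [prfsConstants()].
#' @param phaseRef optional reference phase (radians); a smooth deterministic
#'   background is generated when NULL.
#' @return list(phaseRef, phaseT) in radians, both wrapped to (-pi, pi].
#' @export
synthPhasePair <- function(temp, k = prfsConstants(), phaseRef = NULL) {
  if (is.null(phaseRef)) {
    nu <- nrow(temp); nz <- ncol(temp)
    phaseRef <- outer(sin(seq_len(nu) / nu * 2), cos(seq_len(nz) / nz * 3))
  }
  denom <- 2 * pi * (k$gamma * 1e6) * (k$alpha * 1e-6) * k$B0 * k$TE
  phaseT <- phaseRef + (temp - k$baselineTemp) * denom
  list(phaseRef = wrapPhase(phaseRef), phaseT = wrapPhase(phaseT))
}
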