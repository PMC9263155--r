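#' @import methods
NULL

#' VoxelGrid: a 3D scalar or binary field with geometry
#'
#' The reconstruction target and ground-truth container. A voxel at (1-based)
#' index `(i, j, k)` has its *center* at world position
#' `origin + (c(i, j, k) - 1) * spacing` (mm), matching the NIfTI convention of
#' voxel-center coordinates in a right-handed world frame.
#'
#' @slot values 3D numeric array; binary grids contain only 0/1.
#' @slot spacing voxel spacing in mm, strictly positive, length 3.
#' @slot origin world mm position of the center of voxel (1, 1, 1).
#' @export
setClass("VoxelGrid",
  representation(values = "array", spacing = "numeric", origin = "numeric"))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite numbers")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelGrid
#'
#' @param values 3D array (a scalar such as 0 is recycled to `shape`).
#' @param spacing voxel spacing in mm (length 3).
#' @param origin world mm of the center of voxel (1,1,1); default centers the
#'   grid on the world origin.
#' @param shape integer triple, required when `values` is a scalar.
#' @return A [VoxelGrid-class] object.
#' @examples
#' g <- voxelGrid(0, spacing = c(1, 1, 1), shape = c(16, 16, 16))
#' gridDim(g)
#' @export
voxelGrid <- function(values, spacing = c(1, 1, 1), origin = NULL, shape = NULL) {
  if (length(values) == 1L) {
    if (is.null(shape)) stop("shape is required when values is a scalar")
    values <- array(values, dim = shape)
  }
  if (is.null(dim(values)) || length(dim(values)) != 3L)
    stop("values must be a 3D array")
  if (is.null(origin))
    origin <- -(dim(values) - 1) / 2 * spacing
  new("VoxelGrid", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' ApplicatorAxis: the ablation needle line
#'
#' The applicator's main axis, about which all imaging planes are rotated.
#' Its direction is fixed to the grid z-axis; only the in-plane position
#' varies.
#'
#' @slot center world mm pair (x_c, y_c) where the axis crosses every
#'   axial slice.
#' @export
setClass("ApplicatorAxis", representation(center = "numeric"))

setValidity("ApplicatorAxis", function(object) {
  if (length(object@center) != 2L || any(!is.finite(object@center)))
    "center must be a finite (x_c, y_c) pair" else TRUE
})

#' @param x,y world mm coordinates of the axis.
#' @rdname ApplicatorAxis-class
#' @export
applicatorAxis <- function(x = 0, y = 0) {
  new("ApplicatorAxis", center = c(as.numeric(x), as.numeric(y)))
}

#' OrientedSlice: one 2D image plane containing the applicator axis
#'
#' A slice acquired at rotation `angle` (degrees in \[0, 180)) about the
#' applicator axis. The pixel matrix rows run along the in-plane direction
#' `u` (signed mm offset from the axis along `(cos angle, sin angle)`), the
#' columns along the axis direction z. Pixel `(i, j)` has in-plane
#' coordinates `(origin[1] + (i-1)*spacing[1], origin[2] + (j-1)*spacing[2])`.
#' A single slice therefore covers both half-planes `angle` (u >= 0) and
#' `angle + 180` (u < 0).
#'
#' @slot angle rotation about the applicator axis, degrees in \[0, 180).
#' @slot pixels numeric matrix (u along rows, z along columns).
#' @slot spacing in-plane mm pair (du, dz).
#' @slot thickness out-of-plane slice thickness in mm.
#' @slot timestamp acquisition time in seconds.
#' @slot origin in-plane (u, z) mm of pixel (1, 1) center.
#' @export
setClass("OrientedSlice",
  representation(angle = "numeric", pixels = "matrix", spacing = "numeric",
                 thickness = "numeric", timestamp = "numeric",
                 origin = "numeric"))

setValidity("OrientedSlice", function(object) {
  msg <- character()
  if (object@angle < 0 || object@angle >= 180)
    msg <- c(msg, "angle must lie in [0, 180)")
  if (length(object@spacing) != 2L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 2 positive numbers")
  if (length(object@origin) != 2L)
    msg <- c(msg, "origin must have length 2")
  if (object@thickness <= 0) msg <- c(msg, "thickness must be positive")
  if (length(msg)) msg else TRUE
})

#' @param angle,pixels,spacing,thickness,timestamp,origin see slots.
#'   `origin = NULL` centers the u-range on the axis, placing u = 0 on the
#'   pixel-column lattice (column `floor(nu/2) + 1`), and z symmetric about 0.
#' @rdname OrientedSlice-class
#' @export
orientedSlice <- function(pixels, angle, spacing = c(1, 1), thickness = 5,
                          timestamp = 0, origin = NULL) {
  if (is.null(origin)) {
    nu <- nrow(pixels); nz <- ncol(pixels)
    origin <- c(-floor(nu / 2) * spacing[1], -(nz - 1) / 2 * spacing[2])
  }
  new("OrientedSlice", angle = as.numeric(angle), pixels = pixels,
      spacing = as.numeric(spacing), thickness = as.numeric(thickness),
      timestamp = as.numeric(timestamp), origin = as.numeric(origin))
}

#' OrientedSliceSeries: the sparse rotated-slice input
#'
#' A collection of [OrientedSlice-class] objects grouped by rotation angle and
#' timestamp. Angles must come from the uniform fan `k * 180 / nOrientations`
#' (k = 0, ..., nOrientations - 1) and be unique within each timestamp.
#'
#' @slot slices list of OrientedSlice.
#' @slot nOrientations number of acquired orientations (default 8).
#' @export
setClass("OrientedSliceSeries",
  representation(slices = "list", nOrientations = "integer"))

setValidity("OrientedSliceSeries", function(object) {
  msg <- character()
  if (object@nOrientations < 2L)
    msg <- c(msg, "nOrientations must be >= 2")
  if (length(object@slices)) {
    if (!all(vapply(object@slices, is, logical(1), "OrientedSlice")))
      msg <- c(msg, "slices must all be OrientedSlice objects")
    else {
      ang <- vapply(object@slices, function(s) s@angle, numeric(1))
      ts <- vapply(object@slices, function(s) s@timestamp, numeric(1))
      step <- 180 / object@nOrientations
      if (any(abs(ang / step - round(ang / step)) > 1e-9))
        msg <- c(msg, sprintf(
          "angles must be multiples of 180/nOrientations = %.4f deg", step))
      if (anyDuplicated(paste(round(ang, 6), ts)))
        msg <- c(msg, "angle must be unique within a timestamp")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @param slices,nOrientations see slots.
#' @rdname OrientedSliceSeries-class
#' @export
orientedSliceSeries <- function(slices, nOrientations = 8L) {
  new("OrientedSliceSeries", slices = slices,
      nOrientations = as.integer(nOrientations))
}

#' Ellipse2D: a minimum-volume enclosing ellipse
#'
#' Output of [mveeFit()] for one axial slice. A boundary point p satisfies
#' `t(p - center) %*% shape %*% (p - center) == 1`; the semi-axes are
#' `1/sqrt(sigma_i)` for the singular values of `shape`, with the singular
#' vectors giving the rotation.
#'
#' @slot center mm pair.
#' @slot radii semi-axes (r1, r2) in mm.
#' @slot rotation orthonormal 2x2 basis (columns are the axis directions).
#' @slot shape symmetric positive-definite 2x2 matrix A.
#' @slot degenerate one of "none", "point", "segment" for inputs that do not
#'   determine a proper ellipse (< 3 points, or collinear points).
#' @export
setClass("Ellipse2D",
  representation(center = "numeric", radii = "numeric", rotation = "matrix",
                 shape = "matrix", degenerate = "character"))

setValidity("Ellipse2D", function(object) {
  msg <- character()
  if (!object@degenerate %in% c("none", "point", "segment"))
    msg <- c(msg, "degenerate must be 'none', 'point' or 'segment'")
  if (object@degenerate == "none") {
    if (any(object@radii <= 0)) msg <- c(msg, "radii must be positive")
    A <- object@shape
    if (max(abs(A - t(A))) > 1e-8) msg <- c(msg, "shape must be symmetric")
    sv <- svd(A)$d
    if (max(abs(sort(1 / sqrt(sv)) - sort(object@radii))) > 1e-6)
      msg <- c(msg, "radii inconsistent with shape matrix singular values")
  }
  if (length(msg)) msg else TRUE
})

#' ClosedContour: a closed interpolating spline through ordered vertices
#'
#' Produced by [closedSpline()]. The vertices are ordered by ascending
#' cylindrical angle; the curve is a periodic cubic interpolating B-spline
#' through them, evaluated with de Boor's recursion, and `polygon` is a dense
#' sampling used for winding-number inclusion tests.
#'
#' @slot vertices ordered m x 2 matrix of interpolated points (mm).
#' @slot controls (m+3) x 2 B-spline control points (cyclically extended).
#' @slot knots uniform knot vector.
#' @slot polygon dense n x 2 sampling of the closed curve.
#' @export
setClass("ClosedContour",
  representation(vertices = "matrix", controls = "matrix", knots = "numeric",
                 polygon = "matrix"))

#' TetMesh: a tetrahedral mesh from incremental Delaunay triangulation
#'
#' @slot vertices n x 3 world-mm points.
#' @slot tetrahedra m x 4 vertex indices, positively oriented.
#' @slot boundaryFaces f x 3 vertex indices of the closed boundary surface
#'   (the convex hull of the input points).
#' @export
setClass("TetMesh",
  representation(vertices = "matrix", tetrahedra = "matrix",
                 boundaryFaces = "matrix"))

#' ThresholdPolicy: how per-orientation necrosis thresholds are chosen
#'
#' One of the four policies used when turning temperature slices into binary
#' necrosis masks:
#' \describe{
#'   \item{global}{one fixed threshold for all orientations.}
#'   \item{median}{the median of the eight per-orientation optimal thresholds
#'     is applied to all orientations (robust to outlier thresholds).}
#'   \item{local}{each orientation uses its own optimal threshold.}
#'   \item{ground_truth}{thresholds are bypassed; the input masks come from
#'     reslicing the ground-truth segmentation (perfect-input condition).}
#' }
#'
#' @slot mode one of "global", "median", "local", "ground_truth".
#' @slot globalValue degC, used when mode == "global".
#' @slot localValues per-orientation degC values, used when mode == "local".
#' @export
setClass("ThresholdPolicy",
  representation(mode = "character", globalValue = "numeric",
                 localValues = "numeric"))

setValidity("ThresholdPolicy", function(object) {
  if (!object@mode %in% c("global", "median", "local", "ground_truth"))
    return("mode must be global, median, local or ground_truth")
  if (object@mode == "global" && length(object@globalValue) != 1L)
    return("global mode requires a single globalValue")
  TRUE
})

#' @param mode,globalValue,localValues see slots.
#' @rdname ThresholdPolicy-class
#' @export
thresholdPolicy <- function(mode, globalValue = numeric(),
                            localValues = numeric()) {
  new("ThresholdPolicy", mode = mode, globalValue = as.numeric(globalValue),
      localValues = as.numeric(localValues))
}

#' PhantomSpec: parameters of a synthetic bio-protein phantom experiment
#'
#' Defines a desk-scale emulation of an ex vivo microwave-ablation phantom:
#' an ellipsoidal coagulation zone growing monotonically over the treatment,
#' an analytic radially-decreasing temperature field whose level set at the
#' (angularly varying) coagulation threshold reproduces the ground truth, an
#' optional heat-sink vessel tube, background noise outside the region of
#' interest, and a schedule of corrupted low-SNR "outlier" slices.
#'
#' @slot gridShape integer triple of the ground-truth/reconstruction grid.
#' @slot gridSpacing mm triple.
#' @slot axisCenter world mm (x_c, y_c) of the applicator axis.
#' @slot semiAxesMax final ellipsoid semi-axes (a, c): in-plane radius and
#'   half-length along the axis, mm.
#' @slot centerZ world mm z of the ellipsoid center.
#' @slot tEnd treatment duration, s.
#' @slot growthExponent semi-axes grow as `(t/tEnd)^growthExponent`.
#' @slot baselineTemp degC far-field temperature (room-temperature phantom).
#' @slot peakTemp degC at the applicator.
#' @slot thresholds per-orientation coagulation thresholds, degC in \[50, 60\].
#' @slot nOrientations number of acquired slice orientations.
#' @slot sliceShape pixel matrix dimensions (nu, nz) of each slice.
#' @slot sliceSpacing in-plane mm pair of each slice.
#' @slot sliceThickness mm.
#' @slot noiseSd degC additive Gaussian noise inside the ROI.
#' @slot bgNoiseSd degC extra background noise outside the 60x60 mm ROI.
#' @slot roiSizeMm region-of-interest edge length, mm.
#' @slot vessel list(enabled, center = (x, y), outerDiameter, wall,
#'   coolingRadius, transitionWidth) describing a z-parallel tube and its
#'   cooled sheath, or list(enabled = FALSE).
#' @slot outlierSchedule data.frame(orientation, timestamp) of slices to
#'   corrupt.
#' @slot outlierNoiseFactor multiplier applied to noiseSd on corrupted slices.
#' @slot seed integer seed making the phantom fully deterministic.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", gridSpacing = "numeric",
                 axisCenter = "numeric", semiAxesMax = "numeric",
                 centerZ = "numeric", tEnd = "numeric",
                 growthExponent = "numeric", baselineTemp = "numeric",
                 peakTemp = "numeric", thresholds = "numeric",
                 nOrientations = "integer", sliceShape = "integer",
                 sliceSpacing = "numeric", sliceThickness = "numeric",
                 noiseSd = "numeric", bgNoiseSd = "numeric",
                 roiSizeMm = "numeric", vessel = "list",
                 outlierSchedule = "data.frame",
                 outlierNoiseFactor = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (any(object@thresholds < 50 - 1e-9) || any(object@thresholds > 60 + 1e-9))
    msg <- c(msg, "coagulation thresholds must lie within [50, 60] degC")
  if (length(object@thresholds) != object@nOrientations)
    msg <- c(msg, "one threshold per orientation is required")
  if (any(object@semiAxesMax <= 0))
    msg <- c(msg, "semiAxesMax must be positive")
  if (object@growthExponent <= 0)
    msg <- c(msg, "growthExponent must be positive (necrosis never shrinks)")
  if (object@peakTemp <= max(object@thresholds))
    msg <- c(msg, "peakTemp must exceed every coagulation threshold")
  if (length(msg)) msg else TRUE
})

#' EvaluationReport: results of a phantom x method x policy experiment
#'
#' @slot results one row per (phantom, method, policy) with DSC and, when a
#'   vessel is present, the false-positive vessel volume in ml.
#' @slot summary per (method, policy) group mean DSC, sd, and the 95%
#'   standard-error half-width.
#' @slot semQuantile "normal" (1.96) or "t" quantile used for the half-width.
#' @export
setClass("EvaluationReport",
  representation(results = "data.frame", summary = "data.frame",
                 semQuantile = "character"))
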