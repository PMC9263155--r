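# Accessors and show methods.

#' @describeIn VoxelGrid-class the voxel value array.
#' @param x,object a VoxelGrid.
#' @export
gridValues <- function(x) {
  stopifnot(is(x, "VoxelGrid"))
  x@values
}

#' @describeIn VoxelGrid-class voxel spacing in mm.
#' @export
gridSpacing <- function(x) {
  stopifnot(is(x, "VoxelGrid"))
  x@spacing
}

#' @describeIn VoxelGrid-class world mm of the center of voxel (1,1,1).
#' @export
gridOrigin <- function(x) {
  stopifnot(is(x, "VoxelGrid"))
  x@origin
}

#' @describeIn VoxelGrid-class integer triple (nx, ny, nz).
#' @export
gridDim <- function(x) {
  stopifnot(is(x, "VoxelGrid"))
  dim(x@values)
}

#' @describeIn VoxelGrid-class voxel-center world coordinates along each axis,
#'   as list(x =, y =, z =).
#' @export
gridAxes <- function(x) {
  d <- gridDim(x)
  list(x = x@origin[1] + (seq_len(d[1]) - 1) * x@spacing[1],
       y = x@origin[2] + (seq_len(d[2]) - 1) * x@spacing[2],
       z = x@origin[3] + (seq_len(d[3]) - 1) * x@spacing[3])
}

#' @describeIn VoxelGrid-class TRUE when the grid holds only 0/1 values.
#' @export
isBinaryGrid <- function(x) {
  v <- gridValues(x)
  all(v == 0 | v == 1)
}

#' @describeIn VoxelGrid-class volume of one voxel in ml (1 mm^3 = 0.001 ml).
#' @export
voxelVolumeMl <- function(x) prod(gridSpacing(x)) / 1000

#' Replace the value array of a VoxelGrid, keeping its geometry
#'
#' @param grid a [VoxelGrid-class].
#' @param values replacement array of identical dimensions.
#' @return a VoxelGrid.
#' @export
withGridValues <- function(grid, values) {
  if (!identical(dim(values), dim(grid@values)))
    stop("replacement values must match the grid dimensions")
  new("VoxelGrid", values = values, spacing = grid@spacing,
      origin = grid@origin)
}

setMethod("show", "VoxelGrid", function(object) {
  d <- gridDim(object)
  cat(sprintf("VoxelGrid %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, trim = TRUE), collapse = " x ")))
  cat(sprintf("  origin (%s) mm; values in [%g, %g]%s\n",
              paste(format(object@origin, trim = TRUE), collapse = ", "),
              min(object@values), max(object@values),
              if (isBinaryGrid(object)) " (binary)" else ""))
})

setMethod("show", "ApplicatorAxis", function(object) {
  cat(sprintf("ApplicatorAxis through (%.2f, %.2f) mm, parallel to z\n",
              object@center[1], object@center[2]))
})

#' @describeIn OrientedSliceSeries-class rotation angles (deg) of the slices.
#' @param x,object an OrientedSliceSeries.
#' @export
sliceAngles <- function(x) {
  stopifnot(is(x, "OrientedSliceSeries"))
  vapply(x@slices, function(s) s@angle, numeric(1))
}

#' @describeIn OrientedSliceSeries-class acquisition timestamps (s).
#' @export
sliceTimestamps <- function(x) {
  stopifnot(is(x, "OrientedSliceSeries"))
  vapply(x@slices, function(s) s@timestamp, numeric(1))
}

#' @describeIn OrientedSliceSeries-class subset the series to one timestamp.
#' @param t timestamp in seconds.
#' @export
seriesAtTime <- function(x, t) {
  keep <- abs(sliceTimestamps(x) - t) < 1e-9
  orientedSliceSeries(x@slices[keep], x@nOrientations)
}

setMethod("show", "OrientedSliceSeries", function(object) {
  ts <- unique(sliceTimestamps(object))
  cat(sprintf(
    "OrientedSliceSeries: %d slices, %d orientations, %d timestamp(s)\n",
    length(object@slices), object@nOrientations, length(ts)))
})

setMethod("show", "OrientedSlice", function(object) {
  cat(sprintf(
    "OrientedSlice at %.1f deg, t = %.1f s, %d x %d px (%.2g x %.2g mm)\n",
    object@angle, object@timestamp, nrow(object@pixels), ncol(object@pixels),
    object@spacing[1], object@spacing[2]))
})

#' @describeIn Ellipse2D-class ellipse area (pi * r1 * r2), NA if degenerate.
#' @param x,object an Ellipse2D.
#' @export
ellipseArea <- function(x) {
  stopifnot(is(x, "Ellipse2D"))
  if (x@degenerate != "none") return(NA_real_)
  pi * prod(x@radii)
}

setMethod("show", "Ellipse2D", function(object) {
  if (object@degenerate != "none") {
    cat(sprintf("Ellipse2D (degenerate: %s)\n", object@degenerate))
  } else {
    cat(sprintf(
      "Ellipse2D center (%.2f, %.2f) mm, radii (%.2f, %.2f) mm\n",
      object@center[1], object@center[2], object@radii[1], object@radii[2]))
  }
})

setMethod("show", "TetMesh", function(object) {
  cat(sprintf("TetMesh: %d vertices, %d tetrahedra, %d boundary faces\n",
              nrow(object@vertices), nrow(object@tetrahedra),
              nrow(object@boundaryFaces)))
})

setMethod("show", "ClosedContour", function(object) {
  cat(sprintf("ClosedContour: %d vertices, %d polygon samples\n",
              nrow(object@vertices), nrow(object@polygon)))
})

setMethod("show", "ThresholdPolicy", function(object) {
  cat(sprintf("ThresholdPolicy: %s", object@mode))
  if (object@mode == "global")
    cat(sprintf(" (%.1f degC)", object@globalValue))
  cat("\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: grid %s @ %s mm, %d orientations, tEnd %.0f s, seed %d\n",
    paste(object@gridShape, collapse = "x"),
    paste(format(object@gridSpacing, trim = TRUE), collapse = "x"),
    object@nOrientations, object@tEnd, object@seed))
  cat(sprintf("  necrosis semi-axes (a, c) = (%.1f, %.1f) mm; vessel: %s\n",
              object@semiAxesMax[1], object@semiAxesMax[2],
              if (isTRUE(object@vessel$enabled)) "yes" else "no"))
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  print(object@summary, row.names = FALSE)
})

#' @describeIn EvaluationReport-class per-phantom result rows.
#' @param x an EvaluationReport.
#' @export
reportResults <- function(x) {
  stopifnot(is(x, "EvaluationReport"))
  x@results
}

#' @describeIn EvaluationReport-class per-group summary rows.
#' @export
reportSummary <- function(x) {
  stopifnot(is(x, "EvaluationReport"))
  x@summary
}
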