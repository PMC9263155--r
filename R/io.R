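# NIfTI round-tripping for volumes and slice series. Slice-series metadata
# (angle, timestamp, spacing, thickness, origin) lives in a YAML sidecar
# next to the per-slice 2D NIfTI files; volume geometry is read from the
# NIfTI header, never from configuration.

#' Write a VoxelGrid as NIfTI
#'
#' Spacing goes into pixdim and the origin into an axis-aligned sform
#' (voxel-center convention). Use a `.nii` extension for an uncompressed
#' file.
#'
#' @param grid a [VoxelGrid-class].
#' @param path output file path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeVoxelGrid <- function(grid, path) {
  img <- RNifti::asNifti(gridValues(grid))
  RNifti::pixdim(img) <- gridSpacing(grid)
  m <- diag(4)
  diag(m)[1:3] <- gridSpacing(grid)
  m[1:3, 4] <- gridOrigin(grid)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a VoxelGrid from NIfTI
#'
#' Expects an axis-aligned transform (as written by [writeVoxelGrid()]);
#' rotational components are rejected.
#'
#' @param path NIfTI file path.
#' @return a [VoxelGrid-class].
#' @export
readVoxelGrid <- function(path) {
  img <- RNifti::readNifti(path)
  x <- RNifti::xform(img)
  rot <- x[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-4 || any(diag(rot) < 0))
    stop("only axis-aligned, unflipped NIfTI volumes are supported")
  voxelGrid(array(as.numeric(img), dim = dim(img)),
            spacing = RNifti::pixdim(img)[1:3], origin = x[1:3, 4])
}

#' Write an OrientedSliceSeries to a directory
#'
#' One 2D NIfTI per slice plus a `series.yaml` sidecar recording, per file,
#' the rotation angle (deg), timestamp (s), in-plane spacing, thickness and
#' in-plane origin.
#'
#' @param series an [OrientedSliceSeries-class].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeSliceSeries <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (i in seq_along(series@slices)) {
    s <- series@slices[[i]]
    f <- sprintf("slice_%04d.nii", i)
    RNifti::writeNifti(RNifti::asNifti(s@pixels), file.path(dir, f))
    entries[[i]] <- list(file = f, angle_deg = s@angle,
                         timestamp = s@timestamp,
                         spacing = as.list(s@spacing),
                         thickness = s@thickness,
                         origin = as.list(s@origin))
  }
  yaml::write_yaml(list(n_orientations = series@nOrientations,
                        slices = entries),
                   file.path(dir, "series.yaml"))
  invisible(dir)
}

#' Read an OrientedSliceSeries from a directory written by
#' [writeSliceSeries()]
#'
#' @param dir directory containing `series.yaml` and the slice files.
#' @return an [OrientedSliceSeries-class].
#' @export
readSliceSeries <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "series.yaml"))
  slices <- lapply(meta$slices, function(e) {
    px <- RNifti::readNifti(file.path(dir, e$file))
    orientedSlice(matrix(as.numeric(px), dim(px)[1], dim(px)[2]),
                  angle = e$angle_deg,
                  spacing = unlist(e$spacing), thickness = e$thickness,
                  timestamp = e$timestamp, origin = unlist(e$origin))
  })
  orientedSliceSeries(slices, as.integer(meta$n_orientations))
}
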