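# End-to-end reconstruction pipeline: thermometry -> threshold policy ->
# outlier filtering -> chosen backend.

#' Reconstruct a necrosis volume from binary oriented masks
#'
#' Thin dispatcher over the three mask-based backends. The temperature
#' interpolation baseline consumes temperature slices instead; see
#' [interpReconstruct()].
#'
#' @param masks list of binary [OrientedSlice-class] masks at one timestamp,
#'   already outlier-filtered.
#' @param method "delaunay", "mvee" or "splines".
#' @param grid target [VoxelGrid-class] geometry.
#' @param axis an [ApplicatorAxis-class].
#' @return binary VoxelGrid.
#' @export
reconstructNecrosis <- function(masks, method, grid, axis) {
  switch(match.arg(method, c("delaunay", "mvee", "splines")),
    delaunay = delaunayReconstruct(masks, axis, grid),
    mvee = mveeReconstruct(masks, axis, grid)$volume,
    splines = splineReconstruct(masks, axis, grid)$volume)
}

# Threshold a temperature series into a binary mask series using
# per-orientation thresholds (taus ordered like orientationAngles(n)).
thresholdSeries <- function(series, taus, roiSizeMm, zCenter) {
  angles <- orientationAngles(series@nOrientations)
  slices <- lapply(series@slices, function(s) {
    oi <- which(abs(angles - s@angle) < 1e-9)
    roi <- sliceRoiMask(s, roiSizeMm, zCenter)
    masked <- orientedSlice(thresholdSlice(s@pixels, taus[oi], roi),
                            angle = s@angle, spacing = s@spacing,
                            thickness = s@thickness, timestamp = s@timestamp,
                            origin = s@origin)
    masked
  })
  orientedSliceSeries(slices, series@nOrientations)
}

# Per-orientation optimal thresholds of a phantom's final frame against the
# resliced ground truth.
orientationOptima <- function(finalSlices, gtSlices, roiSizeMm, zCenter,
                              range = c(0, 100), step = 0.5) {
  angles <- vapply(finalSlices, function(s) s@angle, numeric(1))
  vapply(seq_along(finalSlices), function(i) {
    s <- finalSlices[[i]]
    gt <- Filter(function(g) abs(g@angle - s@angle) < 1e-9, gtSlices)[[1]]
    roi <- sliceRoiMask(s, roiSizeMm, zCenter)
    as.numeric(optimalThresholdSearch(s@pixels, gt@pixels, range, step, roi))
  }, numeric(1))[order(angles)]
}

#' Full synthetic-phantom reconstruction with every backend
#'
#' Simulates the phantom's rotated slice series, resolves the threshold
#' policy, filters outlier slices (geometric backends only; the
#' interpolation baseline runs unfiltered as originally published),
#' reconstructs at the final timestamp and scores against the analytic
#' ground truth.
#'
#' @param spec a [PhantomSpec-class].
#' @param methods character vector of backend names.
#' @param policy a [ThresholdPolicy-class].
#' @param timestamps acquisition times; default `c(0.8, 0.9, 1) * tEnd`.
#' @param outlierThresholdPct growth-flagging threshold, percent.
#' @return named list per method: list(volume, dsc, fpMl, note, thresholds,
#'   outlierLog).
#' @export
reconstructPhantom <- function(spec, methods, policy, timestamps = NULL,
                               outlierThresholdPct = 80) {
  if (is.null(timestamps)) timestamps <- c(0.8, 0.9, 1) * spec@tEnd
  tFinal <- max(timestamps)
  grid <- phantomGrid(spec)
  axis <- phantomAxis(spec)
  gt <- generateGroundTruth(spec, tFinal)
  vmask <- if (isTRUE(spec@vessel$enabled)) vesselMask(spec) else NULL
  out <- list()
  geomMethods <- intersect(methods, c("delaunay", "mvee", "splines"))
  score <- function(vol, note = "", taus = NULL, log = NULL) {
    fp <- if (!is.null(vmask))
      vesselFpVolume(vol, subtractVessel(vol, vmask)) else NULL
    list(volume = vol, dsc = diceCoefficient(vol, gt), fpMl = fp,
         note = note, thresholds = taus, outlierLog = log)
  }
  unsupported <- function(note) {
    list(volume = NULL, dsc = NA_real_, fpMl = NA_real_, note = note,
         thresholds = NULL, outlierLog = NULL)
  }
  if (policy@mode == "ground_truth") {
    gtSeries <- resliceGroundTruth(gt, axis, spec@nOrientations,
                                   timestamp = tFinal,
                                   sliceSpacing = c(spec@sliceSpacing[1],
                                                    spec@gridSpacing[3]))
    for (m in geomMethods)
      out[[m]] <- score(reconstructNecrosis(gtSeries@slices, m, grid, axis),
                        note = "resliced ground-truth input")
    if ("interpolation" %in% methods)
      out[["interpolation"]] <-
        unsupported("ground-truth input unsupported for interpolation")
    return(out)
  }
  series <- sampleSliceSeries(spec, timestamps)
  finalSlices <- seriesAtTime(series, tFinal)@slices
  needOptima <- policy@mode %in% c("median", "local") &&
    !length(policy@localValues)
  optima <- NULL
  if (needOptima) {
    gtSeries <- resliceGroundTruth(gt, axis, spec@nOrientations,
                                   timestamp = tFinal,
                                   sliceSpacing = c(spec@sliceSpacing[1],
                                                    spec@gridSpacing[3]))
    optima <- orientationOptima(finalSlices, gtSeries@slices,
                                spec@roiSizeMm, spec@centerZ)
  }
  taus <- resolvePolicy(policy, optima, spec@nOrientations)
  if (length(geomMethods)) {
    maskSeries <- thresholdSeries(series, taus, spec@roiSizeMm, spec@centerZ)
    filtered <- filterSeries(maskSeries, outlierThresholdPct)
    masksFinal <- Filter(function(s) abs(s@timestamp - tFinal) < 1e-9,
                         filtered$slices)
    for (m in geomMethods)
      out[[m]] <- score(reconstructNecrosis(masksFinal, m, grid, axis),
                        taus = taus, log = filtered$log)
  }
  if ("interpolation" %in% methods) {
    if (policy@mode %in% c("local", "ground_truth")) {
      out[["interpolation"]] <- unsupported(sprintf(
        "%s policy unsupported for interpolation", policy@mode))
    } else {
      tau <- unique(taus)[1]
      rec <- interpReconstruct(finalSlices, tau, grid, axis,
                               spec@roiSizeMm, spec@baselineTemp)
      out[["interpolation"]] <- score(rec$volume, taus = taus)
    }
  }
  out
}
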