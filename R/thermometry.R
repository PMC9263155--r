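# PRFS phase-to-temperature mapping, ROI handling, thresholding, and the
# four threshold policies that turn temperature slices into binary
# necrosis masks.

#' PRFS thermometry constants
#'
#' Defaults correspond to a 1.5 T scanner running a GRE sequence with
#' TE = 3.69 ms and the standard proton-resonance-frequency change
#' coefficient of water.
#'
#' @param alpha PRF change coefficient, ppm/degC (negative for water).
#' @param gamma gyromagnetic ratio, MHz/T.
#' @param B0 static field strength, T.
#' @param TE echo time, s.
#' @param baselineTemp degC temperature of the reference acquisition.
#' @return list of constants for [prfsTemperature()].
#' @export
prfsConstants <- function(alpha = -0.01, gamma = 42.58, B0 = 1.5,
                          TE = 3.69e-3, baselineTemp = 20) {
  stopifnot(TE > 0, B0 > 0)
  list(alpha = alpha, gamma = gamma, B0 = B0, TE = TE,
       baselineTemp = baselineTemp)
}

wrapPhase <- function(phi) {
  # wrap to (-pi, pi]
  w <- (phi + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Convert a phase-image pair to a temperature map (PRFS method)
#'
#' The proton resonance frequency of water shifts linearly with temperature,
#' so the phase difference between a gradient-echo image and a reference
#' acquired at baseline temperature encodes the temperature change:
#' `dT = wrap(phase_t - phase_ref) / (2*pi * gamma*1e6 * alpha*1e-6 * B0 * TE)`.
#'
#' @param phaseT phase image at time t, radians (matrix).
#' @param phaseRef reference phase image, radians (same shape).
#' @param k constants from [prfsConstants()].
#' @return temperature map in degC (baseline + dT).
#' @export
prfsTemperature <- function(phaseT, phaseRef, k = prfsConstants()) {
  if (!identical(dim(phaseT), dim(phaseRef)))
    stop("phase images must have the same shape")
  dphi <- wrapPhase(phaseT - phaseRef)
  denom <- 2 * pi * (k$gamma * 1e6) * (k$alpha * 1e-6) * k$B0 * k$TE
  k$baselineTemp + dphi / denom
}

#' Crop a square region of interest around the applicator
#'
#' @param image 2D matrix.
#' @param center pixel pair (i, j) of the applicator position.
#' @param sizeMm ROI edge length in mm (default 60).
#' @param spacing pixel spacing in mm (pair; default 1 mm isotropic).
#' @return the cropped window (matrix).
#' @export
cropRoi <- function(image, center, sizeMm = 60, spacing = c(1, 1)) {
  half <- floor(sizeMm / spacing / 2)
  i0 <- round(center[1]) - half[1]; i1 <- round(center[1]) + half[1] - 1
  j0 <- round(center[2]) - half[2]; j1 <- round(center[2]) + half[2] - 1
  if (i0 < 1 || j0 < 1 || i1 > nrow(image) || j1 > ncol(image))
    stop("ROI exceeds image bounds")
  image[i0:i1, j0:j1, drop = FALSE]
}

#' In-ROI indicator for a slice
#'
#' TRUE for pixels whose in-plane coordinates lie within the square ROI of
#' edge `sizeMm` centered on (u = 0, z = zCenter). Used to suppress
#' background noise outside the phantom before thresholding while keeping
#' the slice geometry intact.
#'
#' @param slice an [OrientedSlice-class].
#' @param sizeMm ROI edge length in mm.
#' @param zCenter mm; ROI center along the axis.
#' @return logical matrix of the slice shape.
#' @export
sliceRoiMask <- function(slice, sizeMm = 60, zCenter = 0) {
  u <- slice@origin[1] + (seq_len(nrow(slice@pixels)) - 1) * slice@spacing[1]
  z <- slice@origin[2] + (seq_len(ncol(slice@pixels)) - 1) * slice@spacing[2]
  outer(abs(u) <= sizeMm / 2, abs(z - zCenter) <= sizeMm / 2, "&")
}

#' Threshold a temperature slice into a necrosis mask
#'
#' Critical-temperature model: `mask = {T >= tau}` (inclusive), followed by
#' 8-connected largest-component filtering to remove speckle.
#'
#' @param temp 2D temperature map, degC.
#' @param tau threshold in degC.
#' @param roi optional logical matrix; pixels outside it are excluded.
#' @return binary matrix.
#' @export
thresholdSlice <- function(temp, tau, roi = NULL) {
  mask <- (temp >= tau) * 1
  if (!is.null(roi)) mask <- mask * roi
  largestComponent(mask)
}

#' Per-orientation optimal threshold by Dice maximization
#'
#' Scans thresholds over `range` at resolution `step` and returns the value
#' maximizing the Dice similarity between the thresholded slice and the
#' corresponding resliced ground-truth plane. Ties are broken toward the
#' larger threshold. An empty ground-truth slice yields the range's upper
#' bound with a warning and attribute `emptyGt = TRUE`.
#'
#' @param temp 2D temperature map, degC.
#' @param gtSlice binary ground-truth plane of the same shape.
#' @param range degC pair, default c(0, 100).
#' @param step scan resolution in degC (default 0.5, below the 1 degC
#'   temperature accuracy of the acquisition).
#' @param roi optional logical ROI matrix passed to [thresholdSlice()].
#' @return optimal threshold in degC (with attribute `dsc`).
#' @export
optimalThresholdSearch <- function(temp, gtSlice, range = c(0, 100),
                                   step = 0.5, roi = NULL) {
  if (!identical(dim(temp), dim(gtSlice)))
    stop("temperature and ground-truth slices must have the same shape")
  if (!any(gtSlice != 0)) {
    warning("empty ground-truth slice; returning the upper threshold bound")
    out <- range[2]
    attr(out, "emptyGt") <- TRUE
    return(out)
  }
  taus <- seq(range[1], range[2], by = step)
  dscs <- vapply(taus, function(tau)
    diceCoefficient(thresholdSlice(temp, tau, roi), gtSlice), numeric(1))
  best <- max(which(dscs >= max(dscs) - 1e-12))  # ties -> larger tau
  out <- taus[best]
  attr(out, "dsc") <- dscs[best]
  out
}

#' Resolve a threshold policy to per-orientation threshold values
#'
#' * `global`: the configured value for every orientation.
#' * `median`: the median of the per-orientation optimal thresholds (for an
#'   even count, the mean of the two central values), applied everywhere —
#'   this reliably removes outlier thresholds caused by local
#'   inhomogeneities.
#' * `local`: the per-orientation optima verbatim.
#' * `ground_truth`: returns `NA` values flagged with attribute
#'   `groundTruth = TRUE`; masks must come from [resliceGroundTruth()]
#'   instead of thresholding.
#'
#' @param policy a [ThresholdPolicy-class].
#' @param perOrientationOptima numeric vector of optimal thresholds (degC),
#'   required for median/local modes.
#' @param nOrientations number of orientations (for global/ground_truth).
#' @return numeric vector of per-orientation thresholds.
#' @export
resolvePolicy <- function(policy, perOrientationOptima = NULL,
                          nOrientations = 8L) {
  switch(policy@mode,
    global = rep(policy@globalValue, nOrientations),
    median = {
      if (is.null(perOrientationOptima) || !length(perOrientationOptima))
        stop("median policy requires the per-orientation optima")
      rep(stats::median(perOrientationOptima),
          length(perOrientationOptima))
    },
    local = {
      vals <- if (length(policy@localValues)) policy@localValues
              else perOrientationOptima
      if (is.null(vals) || !length(vals))
        stop("local policy requires per-orientation values")
      vals
    },
    ground_truth = {
      out <- rep(NA_real_, nOrientations)
      attr(out, "groundTruth") <- TRUE
      out
    })
}
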