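# Relative-growth outlier rejection for single corrupted slices.
#
# The coagulation necrosis is assumed to always grow and never shrink, so a
# large jump in thresholded area between consecutive acquisitions of the
# same orientation marks a corrupted (low-SNR) slice. Flagged slices are
# excluded from the current reconstruction; the comparison baseline is the
# most recent NON-flagged mask of that orientation, so a single corrupted
# frame does not condemn the healthy frame that follows it.

#' Relative area growth between consecutive necrosis masks
#'
#' `deltaA = |A_curr - A_prev| * 100 / A_prev` in percent. By convention,
#' growth from zero area to a positive area is `Inf`, and zero to zero is 0.
#'
#' @param areaCurr,areaPrev areas in mm^2 (non-negative).
#' @return growth in percent.
#' @export
relativeGrowth <- function(areaCurr, areaPrev) {
  if (areaCurr < 0 || areaPrev < 0) stop("areas must be non-negative")
  if (areaPrev == 0) return(if (areaCurr > 0) Inf else 0)
  abs(areaCurr - areaPrev) * 100 / areaPrev
}

#' Is a growth value an outlier?
#'
#' TRUE iff the relative growth strictly exceeds the threshold (default 80%,
#' determined empirically across phantoms; exactly 80% is not flagged).
#'
#' @param deltaPct relative growth in percent.
#' @param thresholdPct flagging threshold in percent.
#' @return logical.
#' @export
isOutlierGrowth <- function(deltaPct, thresholdPct = 80) {
  deltaPct > thresholdPct
}

maskAreaMm2 <- function(slice) {
  sum(slice@pixels != 0) * prod(slice@spacing)
}

#' Filter corrupted slices out of a binary mask series
#'
#' Processes each orientation independently through time. Each mask's area
#' (mm^2, after connected-component denoising) is compared with the most
#' recent accepted mask of the same orientation via [relativeGrowth()];
#' slices exceeding `thresholdPct` are flagged and dropped from the output
#' but retained in the growth log. The first acquisition of an orientation
#' has no predecessor and is never flagged.
#'
#' @param maskSeries [OrientedSliceSeries-class] of binary slices (already
#'   thresholded and component-filtered).
#' @param thresholdPct flagging threshold in percent (default 80).
#' @return list(slices = accepted OrientedSlice list, log = data.frame with
#'   columns orientation, tPrev, tCurr, areaPrev, areaCurr, deltaPct,
#'   outlier).
#' @export
filterSeries <- function(maskSeries, thresholdPct = 80) {
  ang <- sliceAngles(maskSeries)
  ts <- sliceTimestamps(maskSeries)
  keep <- logical(length(maskSeries@slices))
  log <- list()
  for (a in sort(unique(ang))) {
    idx <- which(abs(ang - a) < 1e-9)
    idx <- idx[order(ts[idx])]
    prevArea <- NA_real_; prevT <- NA_real_
    for (i in idx) {
      area <- maskAreaMm2(maskSeries@slices[[i]])
      if (is.na(prevArea)) {
        keep[i] <- TRUE
        delta <- NA_real_; out <- FALSE
      } else {
        delta <- relativeGrowth(area, prevArea)
        out <- isOutlierGrowth(delta, thresholdPct)
        keep[i] <- !out
      }
      log[[length(log) + 1L]] <- data.frame(
        orientation = a, tPrev = prevT, tCurr = ts[i],
        areaPrev = prevArea, areaCurr = area,
        deltaPct = if (is.na(prevArea)) NA_real_ else delta,
        outlier = out)
      if (keep[i]) { prevArea <- area; prevT <- ts[i] }
    }
  }
  list(slices = maskSeries@slices[keep], log = do.call(rbind, log))
}

#' Most recent accepted mask per orientation at or before a timestamp
#'
#' @param filtered result of [filterSeries()].
#' @param t timestamp (s).
#' @return named list of [OrientedSlice-class], keyed by angle.
#' @export
latestAcceptedMasks <- function(filtered, t) {
  out <- list()
  for (s in filtered$slices) {
    if (s@timestamp > t + 1e-9) next
    key <- sprintf("%.6f", s@angle)
    if (is.null(out[[key]]) || out[[key]]@timestamp < s@timestamp)
      out[[key]] <- s
  }
  out
}
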