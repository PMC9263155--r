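# Accuracy, robustness and adaptability metrics, and the experiment driver.

#' Dice similarity coefficient between two binary masks
#'
#' `2|A∩B| / (|A| + |B|)`. Both masks empty returns 1 by convention; exactly
#' one empty returns 0. Accepts plain arrays/matrices or [VoxelGrid-class]
#' objects on the same geometry.
#'
#' @param a,b binary arrays, matrices, or VoxelGrids.
#' @return DSC in \[0, 1\].
#' @export
diceCoefficient <- function(a, b) {
  if (is(a, "VoxelGrid") && is(b, "VoxelGrid")) {
    if (!identical(gridDim(a), gridDim(b)) ||
        max(abs(gridSpacing(a) - gridSpacing(b))) > 1e-9 ||
        max(abs(gridOrigin(a) - gridOrigin(b))) > 1e-9)
      stop("masks must share the same grid geometry")
    a <- gridValues(a); b <- gridValues(b)
  }
  if (!identical(dim(a), dim(b))) stop("masks must have the same shape")
  na <- sum(a != 0); nb <- sum(b != 0)
  if (na + nb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (na + nb)
}

#' Mean and 95% standard-error half-width of a group of values
#'
#' The standard error of the mean `sd/sqrt(n)` scaled by the two-sided 95%
#' quantile — normal (1.96) by default, or the t distribution with n - 1
#' degrees of freedom.
#'
#' @param values numeric vector, length >= 2.
#' @param quantile "normal" or "t".
#' @return list(mean, sd, sem95, n).
#' @export
sem95 <- function(values, quantile = c("normal", "t")) {
  quantile <- match.arg(quantile)
  n <- length(values)
  if (n < 2) stop("sem95 requires at least two values")
  s <- stats::sd(values)
  q <- if (quantile == "normal") stats::qnorm(0.975) else stats::qt(0.975, n - 1)
  list(mean = mean(values), sd = s, sem95 = q * s / sqrt(n), n = n)
}

#' False-positive vessel volume of a reconstruction
#'
#' Volume (ml) of voxels present in the reconstruction without a-priori
#' vessel knowledge but absent from the reconstruction with the vessel mask
#' subtracted; this equals the reconstructed volume that intrudes into the
#' vessel.
#'
#' @param reconWithout binary [VoxelGrid-class], no a-priori knowledge.
#' @param reconWith binary VoxelGrid with the vessel subtracted.
#' @return false-positive volume in ml.
#' @export
vesselFpVolume <- function(reconWithout, reconWith) {
  if (!identical(gridDim(reconWithout), gridDim(reconWith)))
    stop("reconstructions must share the same grid geometry")
  fp <- sum(gridValues(reconWithout) != 0 & gridValues(reconWith) == 0)
  fp * voxelVolumeMl(reconWithout)
}

#' Subtract a vessel mask from a reconstruction (a-priori knowledge)
#'
#' @param recon binary [VoxelGrid-class].
#' @param vessel binary VoxelGrid of the vessel tube.
#' @return binary VoxelGrid with vessel voxels cleared.
#' @export
subtractVessel <- function(recon, vessel) {
  if (!identical(gridDim(recon), gridDim(vessel)))
    stop("reconstruction and vessel mask must share the same grid geometry")
  withGridValues(recon, gridValues(recon) * (gridValues(vessel) == 0))
}

#' Run a phantoms x methods x policy reconstruction experiment
#'
#' For each synthetic phantom, simulates the rotated slice series, resolves
#' the threshold policy, applies outlier filtering (for the Delaunay, MVEE
#' and spline backends; the temperature-interpolation baseline runs
#' unfiltered, as originally published), reconstructs the necrosis volume at
#' the final timestamp, and scores it against the analytic ground truth.
#' Unsupported method/policy combinations (interpolation with local or
#' ground-truth input) are skipped with a note in the results.
#'
#' @param phantoms list of [PhantomSpec-class] objects.
#' @param methods character subset of
#'   c("interpolation", "delaunay", "mvee", "splines").
#' @param policy a [ThresholdPolicy-class].
#' @param includeOutlierPhantoms if FALSE, phantoms whose spec schedules
#'   corrupted slices are excluded from the group summary.
#' @param timestamps acquisition times (s); default three frames ending at
#'   each phantom's tEnd.
#' @param semQuantile "normal" or "t" for the group half-width.
#' @return an [EvaluationReport-class].
#' @export
runExperiment <- function(phantoms, methods, policy,
                          includeOutlierPhantoms = TRUE,
                          timestamps = NULL,
                          semQuantile = c("normal", "t")) {
  semQuantile <- match.arg(semQuantile)
  rows <- list()
  for (pi in seq_along(phantoms)) {
    spec <- phantoms[[pi]]
    corrupted <- nrow(spec@outlierSchedule) > 0
    if (!includeOutlierPhantoms && corrupted) next
    pr <- reconstructPhantom(spec, methods, policy, timestamps)
    for (m in names(pr)) {
      rows[[length(rows) + 1L]] <- data.frame(
        phantom = pi, method = m, policy = policy@mode,
        dsc = pr[[m]]$dsc,
        fpMl = if (is.null(pr[[m]]$fpMl)) NA_real_ else pr[[m]]$fpMl,
        corrupted = corrupted, note = pr[[m]]$note,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  results <- results[order(results$method, results$phantom), ]
  ok <- !is.na(results$dsc)
  groups <- split(results[ok, ], results$method[ok])
  summ <- do.call(rbind, lapply(names(groups), function(m) {
    v <- groups[[m]]$dsc
    if (length(v) >= 2) {
      s <- sem95(v, semQuantile)
      data.frame(method = m, policy = policy@mode, n = s$n,
                 meanDsc = s$mean, sd = s$sd, sem95 = s$sem95,
                 meanFpMl = mean(groups[[m]]$fpMl, na.rm = TRUE))
    } else {
      data.frame(method = m, policy = policy@mode, n = length(v),
                 meanDsc = mean(v), sd = NA_real_, sem95 = NA_real_,
                 meanFpMl = mean(groups[[m]]$fpMl, na.rm = TRUE))
    }
  }))
  new("EvaluationReport", results = results, summary = summ,
      semQuantile = semQuantile)
}
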