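#' Scalar curve-shape characteristics
#'
#' Four descriptors of a smoothed 541-point calcium curve:
#' \describe{
#'   \item{magnitude}{max minus min, nM — the size of the response.}
#'   \item{tmax}{time of the (first) maximum as a fraction of the 540 s
#'     record; early values flag early saturation.}
#'   \item{ylast}{terminal value scaled by the magnitude; below 1 flags a
#'     transient (decaying) response.}
#'   \item{absdev}{mean absolute deviation of the min-max scaled curve from
#'     the straight chord joining its first and last scaled values;
#'     0 for a linear curve, large for non-monotone shapes.}
#' }
#' tmax, ylast and absdev are computed on the min-max scaled curve and are
#' therefore invariant to affine rescaling of the input.
#'
#' @param smoothed A 541-point `"uniform_curve"` (nM) or `"scaled_curve"`.
#' @param threshold Degeneracy threshold on the range (nM): a flat curve
#'   gets magnitude 0 and `NA` shape features, flagged via `degenerate`.
#' @return List of class `"scalar_features"`: `magnitude`, `tmax`, `ylast`,
#'   `absdev`, `degenerate`.
#' @export
compute_scalar_features <- function(smoothed, threshold = 1e-6) {
  y <- smoothed$values
  stopifnot(length(y) == 541)
  if (inherits(smoothed, "scaled_curve")) {
    # report magnitude on the original nM scale
    mag <- smoothed$scale_range
    lo <- min(y); hi <- max(y)
  } else {
    lo <- min(y); hi <- max(y)
    mag <- hi - lo
  }
  if (hi - lo <= (if (inherits(smoothed, "scaled_curve")) 0 else threshold) ||
      mag <= threshold) {
    return(structure(list(magnitude = 0, tmax = NA_real_, ylast = NA_real_,
                          absdev = NA_real_, degenerate = TRUE),
                     class = "scalar_features"))
  }
  s <- (y - lo) / (hi - lo)
  tmax <- (which.max(s) - 1L) / 540      # first maximum on ties
  ylast <- s[541]
  chord <- s[1] + (s[541] - s[1]) * (0:540) / 540
  absdev <- mean(abs(s - chord))
  structure(list(magnitude = mag, tmax = tmax, ylast = ylast,
                 absdev = absdev, degenerate = FALSE),
            class = "scalar_features")
}

#' @export
print.scalar_features <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate (flat) curve: magnitude 0\n")
  } else {
    cat(sprintf("magnitude %.1f nM, tmax %.3f, ylast %.3f, absdev %.4f\n",
                x$magnitude, x$tmax, x$ylast, x$absdev))
  }
  invisible(x)
}

#' Scalar feature table for a set of curves
#'
#' @param curves List of smoothed `"uniform_curve"`s.
#' @return Data frame with columns `exp_id`, `magnitude_nM`, `tmax`,
#'   `ylast`, `absdev`.
#' @export
scalar_feature_table <- function(curves) {
  rows <- lapply(curves, function(cv) {
    f <- compute_scalar_features(cv)
    data.frame(exp_id = cv$exp_id, magnitude_nM = f$magnitude,
               tmax = f$tmax, ylast = f$ylast, absdev = f$absdev)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`; negative values indicate a prediction worse than
#' the mean of the observations. Used per curve for trend fits and across
#' curves for magnitude fits.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return The R-squared statistic (may be negative).
#' @export
r2_score <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed values are constant; R^2 undefined")
  1 - sum((observed - predicted)^2) / ss_tot
}
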