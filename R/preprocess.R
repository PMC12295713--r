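#' Resample a raw curve to uniform 1 s steps
#'
#' Linear interpolation at integer seconds 0..540 (541 points). Raw samples
#' must span the full window; extrapolation beyond the sampled range is
#' refused unless `clamp = TRUE`, which repeats the terminal values.
#'
#' @param raw A `"raw_curve"`.
#' @param clamp Allow clamp-extrapolation outside the sampled range.
#' @return A list of class `"uniform_curve"`: `exp_id`, `values` (541 nM
#'   values at t = 0..540 s).
#' @export
resample <- function(raw, clamp = FALSE) {
  stopifnot(length(raw$times) >= 2, length(raw$times) == length(raw$values))
  tt <- 0:540
  if (!clamp && (min(raw$times) > 0 || max(raw$times) < 540)) {
    stop("curve ", raw$exp_id, " does not span 0-540 s; ",
         "set clamp = TRUE to extrapolate by clamping")
  }
  v <- stats::approx(raw$times, raw$values, xout = tt, rule = 2)$y
  structure(list(exp_id = raw$exp_id, values = v), class = "uniform_curve")
}

#' Savitzky-Golay smoothing of a uniform curve
#'
#' Local least-squares polynomial smoothing; a polynomial of degree at most
#' `polyorder` passes through unchanged. Defaults (11 s window, cubic)
#' preserve the fastest thrombin transients at 1 Hz while removing
#' measurement jitter.
#'
#' @param curve A `"uniform_curve"`.
#' @param window_s Odd window length in seconds (samples at 1 Hz).
#' @param polyorder Polynomial order, less than `window_s`.
#' @return A smoothed `"uniform_curve"`.
#' @export
smooth_curve <- function(curve, window_s = 11, polyorder = 3) {
  if (window_s %% 2 == 0 || window_s <= polyorder) {
    stop("window must be odd and greater than the polynomial order")
  }
  v <- signal::sgolayfilt(curve$values, p = polyorder, n = window_s)
  structure(list(exp_id = curve$exp_id, values = v), class = "uniform_curve")
}

#' Per-curve min-max scaling
#'
#' Maps a smoothed curve onto \[0, 1\] and stores the back-transform
#' constants. Scaling is per time series: every scaled curve spans exactly
#' \[0, 1\].
#'
#' @param curve A `"uniform_curve"`.
#' @param threshold Degeneracy threshold on the range (nM); flat curves
#'   (e.g. a zero-noise vehicle control) are rejected with the offending id.
#' @return A list of class `"scaled_curve"`: `exp_id`, `values` in \[0,1\],
#'   `scale_min` (nM), `scale_range` (nM).
#' @export
minmax_scale <- function(curve, threshold = 1e-6) {
  lo <- min(curve$values); hi <- max(curve$values)
  if (hi - lo <= threshold) {
    stop("degenerate (flat) curve for experiment ", curve$exp_id)
  }
  structure(list(exp_id = curve$exp_id,
                 values = (curve$values - lo) / (hi - lo),
                 scale_min = lo, scale_range = hi - lo),
            class = "scaled_curve")
}

#' Invert min-max scaling
#'
#' @param scaled A `"scaled_curve"`.
#' @return The smoothed `"uniform_curve"` in nM.
#' @export
unscale <- function(scaled) {
  structure(list(exp_id = scaled$exp_id,
                 values = scaled$values * scaled$scale_range +
                   scaled$scale_min),
            class = "uniform_curve")
}

#' Quadratic feature expansion of scaled conditions
#'
#' Expands the 6 scaled condition channels (col, crp, thr, egta, ai, thap)
#' into the 27 network inputs: the 6 linear terms, their 6 squares and the
#' 15 unordered pairwise products, in that fixed order (cross terms
#' lexicographic by channel index).
#'
#' @param scaled One row (or a data frame of rows) from
#'   [scale_conditions()]; the drug flag, if present, is ignored (the
#'   networks never see it).
#' @return A numeric matrix with one 27-column row per condition, with
#'   descriptive column names.
#' @export
expand_features <- function(scaled) {
  chans <- c("col", "crp", "thr", "egta", "ai", "thap")
  if (!all(chans %in% names(scaled))) {
    stop("expected the 6 scaled condition channels: ",
         paste(chans, collapse = ", "))
  }
  X <- as.matrix(scaled[, chans, drop = FALSE])
  n <- nrow(X)
  sq <- X^2
  colnames(sq) <- paste0(chans, "^2")
  cross <- matrix(0, n, 15)
  nm <- character(15)
  k <- 0L
  for (i in 1:5) for (j in (i + 1):6) {
    k <- k + 1L
    cross[, k] <- X[, i] * X[, j]
    nm[k] <- paste0(chans[i], ":", chans[j])
  }
  colnames(cross) <- nm
  out <- cbind(X, sq, cross)
  rownames(out) <- if ("exp_id" %in% names(scaled)) scaled$exp_id else NULL
  out
}

#' Preprocess raw curves end to end
#'
#' Resample to 1 s, smooth, and min-max scale each curve.
#'
#' @param curves List of `"raw_curve"` objects.
#' @param window_s,polyorder Savitzky-Golay settings.
#' @return List with `uniform` (smoothed `"uniform_curve"`s) and `scaled`
#'   (`"scaled_curve"`s), both named by `exp_id`.
#' @export
preprocess_curves <- function(curves, window_s = 11, polyorder = 3) {
  uniform <- lapply(curves, function(cv)
    smooth_curve(resample(cv), window_s, polyorder))
  scaled <- lapply(uniform, minmax_scale)
  list(uniform = uniform, scaled = scaled)
}
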