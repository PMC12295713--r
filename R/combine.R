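#' Reconstruct a nanomolar calcium curve from the two networks
#'
#' The trend network supplies the 0-1 scaled shape (clipped to \[0, 1\],
#' with the clipped fraction recorded), the magnitude network the nM range;
#' the curve is `offset + trend * magnitude`. For de novo prediction the
#' offset is 0: the networks model the response range above resting level,
#' not absolute resting calcium.
#'
#' @param mlp A fitted `"ca_mlp"`.
#' @param narx A fitted `"ca_narx"`.
#' @param conditions Scaled condition data frame or 27-column feature
#'   matrix (both networks must share the feature convention).
#' @param offset Baseline offset in nM added to every curve (e.g. a stored
#'   curve minimum); default 0.
#' @return Matrix (conditions x 541) of predicted nM values, with
#'   attributes `magnitude` (nM vector) and `clip_fraction` (fraction of
#'   simulated points clipped into \[0, 1\]).
#' @export
predict_nm_curve <- function(mlp, narx, conditions, offset = 0) {
  X <- if (is.matrix(conditions)) conditions else expand_features(conditions)
  trend <- predict(narx, X)
  clip_fraction <- mean(trend < 0 | trend > 1)
  trend <- pmin(pmax(trend, 0), 1)
  magnitude <- predict(mlp, X, type = "nM")
  out <- offset + trend * magnitude
  attr(out, "magnitude") <- magnitude
  attr(out, "clip_fraction") <- clip_fraction
  out
}

#' One-at-a-time sensitivity sweep
#'
#' Varies one agonist at a time over a low-dose fraction grid (default 1-10
#' percent of the maximal training concentrations: 30 ug/mL collagen, 10
#' ug/mL CRP, 10 nM thrombin) at every combination of the three inhibitor
#' flags (2^3 = 8), holding everything else at baseline. For each cell the
#' combined networks predict the nM curve and its four scalar
#' characteristics.
#'
#' @param mlp,narx Fitted networks.
#' @param fractions Dose fractions of the per-agonist maximum, all within
#'   \[0, 0.1\] by default convention (values in \[0, 1\] are accepted).
#' @param max_doses Named per-agonist maximal doses.
#' @return Object of class `"oat_result"`: a long data frame (`agonist`,
#'   `egta`, `ai`, `thap`, `fraction`, `dose`, `magnitude_nM`,
#'   `log10_magnitude`, `tmax`, `ylast`, `absdev`) plus the predicted
#'   curves as attribute `curves`.
#' @export
oat_sweep <- function(mlp, narx, fractions = seq(0.01, 0.10, by = 0.01),
                      max_doses = default_design_spec()$max_doses) {
  if (any(fractions < 0 | fractions > 1)) {
    stop("dose fractions must lie within [0, 1] of the maximum")
  }
  flags <- expand_flags(full = TRUE)
  agonists <- c("collagen", "crp", "thrombin")
  rows <- list(); curves <- list()
  for (ag in agonists) for (i in seq_len(nrow(flags))) for (fr in fractions) {
    cond <- cond_row(ag, fr * max_doses[[ag]], flags[i, ])
    cond$exp_id <- 0L
    if (fr == 0) cond$agonist <- "none"   # zero dose = vehicle baseline
    sc <- scale_conditions(validate_conditions(cond), max_doses)
    curve <- predict_nm_curve(mlp, narx, sc)
    sf <- compute_scalar_features(
      structure(list(exp_id = 0L, values = curve[1, ]),
                class = "uniform_curve"))
    rows[[length(rows) + 1L]] <- data.frame(
      agonist = ag, egta = flags[i, "egta"], ai = flags[i, "ai"],
      thap = flags[i, "thap"], fraction = fr, dose = fr * max_doses[[ag]],
      magnitude_nM = sf$magnitude,
      log10_magnitude = log10(max(sf$magnitude, .Machine$double.eps)),
      tmax = sf$tmax, ylast = sf$ylast, absdev = sf$absdev)
    curves[[length(curves) + 1L]] <- curve[1, ]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  class(out) <- c("oat_result", class(out))
  out
}

#' Heatmap-style matrix of one OAT characteristic
#'
#' Reshapes an [oat_sweep()] result into an (agonist x inhibitor
#' combination) by dose-fraction matrix for one characteristic.
#'
#' @param oat An `"oat_result"`.
#' @param feature One of `"log10_magnitude"`, `"tmax"`, `"ylast"`,
#'   `"absdev"`.
#' @return Numeric matrix, rows labelled `agonist[egta ai thap]`, columns
#'   by dose fraction.
#' @export
oat_matrix <- function(oat, feature = c("log10_magnitude", "tmax", "ylast",
                                        "absdev")) {
  feature <- match.arg(feature)
  key <- paste0(oat$agonist, "[", oat$egta, " ", oat$ai, " ", oat$thap, "]")
  fr <- sort(unique(oat$fraction))
  rows <- unique(key)
  mat <- matrix(NA_real_, length(rows), length(fr),
                dimnames = list(rows, paste0(100 * fr, "%")))
  for (i in seq_len(nrow(oat))) {
    mat[key[i], paste0(100 * oat$fraction[i], "%")] <- oat[[feature]][i]
  }
  mat
}
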