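#' Default parameters of the synthetic calcium-curve generator
#'
#' The generator emulates the qualitative structure of calibrated Fura-2
#' platelet traces: dose-dependent rises, transient (decaying) thrombin
#' responses versus monotone collagen/CRP responses, amplitudes lowered up
#' to several-fold by extracellular calcium chelation (EGTA) and moderately
#' by autocrine-mediator blockade (AI), and sustained store-operated-entry
#' driven rises with thapsigargin plus CaCl2. Amplitudes and time constants
#' are phenomenological defaults in nM and seconds; users with real
#' calibrated data replace the generator entirely.
#'
#' @param baseline Resting cytosolic calcium, nM.
#' @param noise_sd Additive Gaussian measurement noise, nM (truncated at 0).
#' @param egta_amp_factor,ai_amp_factor,drug_amp_factor Multiplicative
#'   amplitude factors applied under EGTA, AI, or the entry-blocking drug.
#' @param thap_amp Sustained amplitude added by thapsigargin, nM.
#' @param agonists Per-agonist shape parameters: maximal amplitude `amp_max`
#'   (nM), half-maximal dose `ec50` (dose units), Hill coefficient `hill`,
#'   rise time constant `tau_rise` (s), sustained terminal fraction `s_end`
#'   in \[0,1\], decay time constant `tau_decay` (s) and onset `lag` (s).
#' @return A list of class `"generator_params"`.
#' @export
generator_params <- function(baseline = 60, noise_sd = 3,
                             egta_amp_factor = 0.3, ai_amp_factor = 0.7,
                             drug_amp_factor = 0.3, thap_amp = 250,
                             agonists = NULL) {
  if (is.null(agonists)) {
    agonists <- list(
      collagen = list(amp_max = 300, ec50 = 5,   hill = 1.5, tau_rise = 120,
                      s_end = 0.95, tau_decay = 300, lag = 30),
      crp      = list(amp_max = 500, ec50 = 2,   hill = 1.5, tau_rise = 60,
                      s_end = 0.90, tau_decay = 250, lag = 20),
      thrombin = list(amp_max = 600, ec50 = 1.5, hill = 1.2, tau_rise = 25,
                      s_end = 0.35, tau_decay = 120, lag = 10)
    )
  }
  p <- list(baseline = baseline, noise_sd = noise_sd,
            egta_amp_factor = egta_amp_factor, ai_amp_factor = ai_amp_factor,
            drug_amp_factor = drug_amp_factor, thap_amp = thap_amp,
            thap_tau_rise = 150, thap_lag = 20, agonists = agonists)
  for (a in p$agonists) {
    stopifnot(a$tau_rise > 0, a$tau_decay > 0,
              a$s_end >= 0, a$s_end <= 1, a$amp_max >= 0)
  }
  stopifnot(egta_amp_factor >= 0, ai_amp_factor >= 0, drug_amp_factor >= 0,
            noise_sd >= 0)
  class(p) <- "generator_params"
  p
}

#' Hill dose-response fraction
#'
#' `dose^h / (dose^h + ec50^h)`: 0 at zero dose, 0.5 at the half-maximal
#' dose, saturating towards 1; monotone in dose.
#'
#' @param dose Dose (same units as `ec50`), non-negative.
#' @param ec50 Half-maximal dose, positive.
#' @param hill Hill coefficient, positive.
#' @return Effect fraction in \[0, 1\].
#' @export
dose_response <- function(dose, ec50, hill) {
  if (any(dose < 0)) stop("negative dose")
  stopifnot(ec50 > 0, hill > 0)
  dh <- dose^hill
  dh / (dh + ec50^hill)
}

# noiseless curve family evaluated at arbitrary times (the closed form the
# noisy generator adds jitter to; also serves as the analytic oracle)
curve_family <- function(times, condition, params) {
  ag <- condition$agonist
  egta <- condition$egta; ai <- condition$ai
  thap <- condition$thap; drug <- condition$drug
  mod <- (if (egta == 1) params$egta_amp_factor else 1) *
         (if (ai == 1) params$ai_amp_factor else 1) *
         (if (drug == 1) params$drug_amp_factor else 1)
  y <- rep(0, length(times))
  if (ag != "none" && condition$dose > 0) {
    a <- params$agonists[[ag]]
    A <- a$amp_max * dose_response(condition$dose, a$ec50, a$hill) * mod
    r <- 1 - exp(-pmax(0, times - a$lag) / a$tau_rise)
    # with thapsigargin and CaCl2, blocked store re-uptake removes the decay
    s_end <- if (thap == 1 && egta == 0) 1 else a$s_end
    t_peak <- a$lag + 3 * a$tau_rise
    d <- s_end + (1 - s_end) * exp(-pmax(0, times - t_peak) / a$tau_decay)
    y <- y + A * r * d
  }
  if (thap == 1) {
    At <- params$thap_amp * mod
    y <- y + At * (1 - exp(-pmax(0, times - params$thap_lag) /
                             params$thap_tau_rise))
  }
  params$baseline + y
}

#' Generate one synthetic calcium curve
#'
#' Deterministic given `seed`: the closed-form curve family evaluated on the
#' raw sampling grid (2 s for thrombin, 4 s otherwise, 0-540 s) plus i.i.d.
#' Gaussian noise truncated at 0 nM.
#'
#' @param condition One row of a condition data frame.
#' @param params [generator_params()] object.
#' @param seed Integer seed for the noise.
#' @return A list of class `"raw_curve"`: `exp_id`, `times` (s), `values`
#'   (nM), `sampling_interval` (s).
#' @export
generate_curve <- function(condition, params = generator_params(), seed = 1L) {
  stopifnot(inherits(params, "generator_params"))
  dt <- if (condition$agonist == "thrombin") 2 else 4
  times <- seq(0, 540, by = dt)
  y <- curve_family(times, condition, params)
  if (params$noise_sd > 0) {
    old <- .Random.seed_save()
    set.seed(seed)
    y <- y + stats::rnorm(length(y), sd = params$noise_sd)
    .Random.seed_restore(old)
  }
  out <- list(exp_id = condition$exp_id, times = times,
              values = pmax(y, 0), sampling_interval = dt)
  class(out) <- "raw_curve"
  out
}

# save/restore the global RNG state so generation with an explicit seed does
# not perturb the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a full synthetic dataset
#'
#' One curve per condition, with per-condition sub-seeds derived
#' reproducibly from the master seed.
#'
#' @param conditions Condition data frame.
#' @param params [generator_params()] object.
#' @param seed Master integer seed.
#' @return Named list of `"raw_curve"` objects (names are `exp_id`s).
#' @export
generate_dataset <- function(conditions, params = generator_params(),
                             seed = 1L) {
  stopifnot(nrow(conditions) > 0)
  if (anyDuplicated(conditions$exp_id)) stop("duplicate exp_id")
  old <- .Random.seed_save()
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max, nrow(conditions))
  .Random.seed_restore(old)
  curves <- lapply(seq_len(nrow(conditions)), function(i) {
    generate_curve(conditions[i, ], params, seed = subseeds[i])
  })
  names(curves) <- conditions$exp_id
  curves
}

#' @export
print.raw_curve <- function(x, ...) {
  cat(sprintf("Raw [Ca2+]i curve (exp %s): %d samples at %g s, %.0f-%.0f nM\n",
              x$exp_id, length(x$times), x$sampling_interval,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.raw_curve <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "l", xlab = "time (s)",
                 ylab = "[Ca2+]i (nM)",
                 main = paste("Experiment", x$exp_id), ...)
  invisible(x)
}
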