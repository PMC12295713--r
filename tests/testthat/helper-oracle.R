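# Independent brute-force recursion of the closed-loop trend network:
# a literal per-step transcription of the layered recurrence, scalar
# condition at a time, kept free of the package's simulation code path.
oracle_narx_recursion <- function(m, x, horizon) {
  y <- numeric(horizon)
  for (t in seq_len(horizon)) {
    yh <- vapply(m$delays, function(d) if (t - d >= 1) y[t - d] else 0, 0)
    a1 <- tanh(drop(m$H1 %*% yh) + drop(m$W %*% x) + m$b1)
    a2 <- tanh(drop(m$H2 %*% yh) + drop(m$L2 %*% a1) + m$b2)
    a3 <- tanh(drop(m$H3 %*% yh) + drop(m$L3 %*% a2) + m$b3)
    y[t] <- sum(m$L4 * a3) + m$b4
  }
  y
}

# random small trend-network parameter set (moderate weights so tanh stays
# out of deep saturation)
random_small_narx <- function(arch = c(3, 4, 2), n_in = 27L, seed = 1,
                              scale = 0.5) {
  set.seed(seed)
  rm_ <- function(r, c) matrix(stats::rnorm(r * c, sd = scale / sqrt(c)), r, c)
  nd <- length(platecal::default_delays())
  list(W = rm_(arch[1], n_in), H1 = rm_(arch[1], nd),
       L2 = rm_(arch[2], arch[1]), H2 = rm_(arch[2], nd),
       L3 = rm_(arch[3], arch[2]), H3 = rm_(arch[3], nd),
       L4 = stats::rnorm(arch[3], sd = scale / sqrt(arch[3])),
       b1 = stats::rnorm(arch[1], sd = 0.1),
       b2 = stats::rnorm(arch[2], sd = 0.1),
       b3 = stats::rnorm(arch[3], sd = 0.1),
       b4 = stats::rnorm(1, sd = 0.1),
       arch = arch, delays = platecal::default_delays(), n_in = n_in)
}

# uniform curve wrapper for hand-built 541-point series
as_uniform <- function(values, exp_id = 0L) {
  structure(list(exp_id = exp_id, values = values), class = "uniform_curve")
}

# full desk-scale pipeline run (training included); built once per test run
shared_pipeline <- function(seed = 1) {
  if (is.null(shared_cache$pipe)) {
    dir <- file.path(tempdir(), "platecal-pipeline")
    cfg <- pipeline_config(seed = seed, out_dir = dir)
    shared_cache$pipe <- run_pipeline(cfg)
    shared_cache$pipe_dir <- dir
  }
  shared_cache$pipe
}

# shared small preprocessed dataset; built once per test run
shared_cache <- new.env()
shared_dataset <- function() {
  if (is.null(shared_cache$ds)) {
    conditions <- build_design_matrix()
    curves <- generate_dataset(conditions, generator_params(), seed = 101)
    prep <- preprocess_curves(curves)
    scaled_cond <- scale_conditions(conditions)
    shared_cache$ds <- list(
      conditions = conditions, curves = curves, prep = prep,
      scaled_cond = scaled_cond, X27 = expand_features(scaled_cond),
      features = scalar_feature_table(prep$uniform),
      splits = assign_splits(conditions))
  }
  shared_cache$ds
}
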