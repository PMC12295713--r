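# hand-built model with identity input normalisation
make_mlp <- function(W, b1, v, b2, n_in = ncol(W)) {
  m <- list(hidden_weights = W, hidden_bias = b1, output_weights = v,
            output_bias = b2, n_nodes = nrow(W), activation = "relu",
            input_norm = list(lo = rep(-1, n_in), range = rep(2, n_in)),
            members = list(list(hidden_weights = W, hidden_bias = b1,
                                output_weights = v, output_bias = b2,
                                n_nodes = nrow(W))))
  class(m) <- "ca_mlp"
  m
}

test_that("the rectifier forward pass matches independent step-by-step arithmetic", {
  # all-zero parameters give zero output for any input
  z <- make_mlp(matrix(0, 2, 27), c(0, 0), c(0, 0), 0)
  expect_equal(mlp_forward(z, runif(27)), 0)
  # a dead rectifier (negative pre-activation) passes only the output bias
  dead <- make_mlp(matrix(-1, 1, 3), -5, 2, 0.7, n_in = 3)
  expect_equal(mlp_forward(dead, c(1, 1, 1)), 0.7)
  # two-node model against hand arithmetic
  W <- rbind(c(0.5, -0.2, 0.1), c(-0.3, 0.4, 0.2))
  b1 <- c(0.1, -0.05)
  v <- c(1.5, -2)
  x <- c(0.8, 0.6, -0.4)
  z1 <- 0.5 * 0.8 - 0.2 * 0.6 + 0.1 * (-0.4) + 0.1
  z2 <- -0.3 * 0.8 + 0.4 * 0.6 + 0.2 * (-0.4) - 0.05
  by_hand <- 1.5 * max(z1, 0) - 2 * max(z2, 0) + 0.25
  m <- make_mlp(W, b1, v, 0.25, n_in = 3)
  expect_equal(mlp_forward(m, x), by_hand, tolerance = 1e-12)
  expect_error(mlp_forward(m, c(1, 2)), "arity")
})

test_that("training drives a noiseless linear target to near-zero cost", {
  set.seed(11)
  X <- matrix(runif(40 * 27, 0, 1), 40, 27)
  y <- rowSums(X)
  fit <- fit_mlp(list(features = X, targets = y),
                 list(features = X, targets = y),
                 node_range = 3, restarts = 5, seed = 2, ensemble = 1,
                 max_chunks = 80)
  expect_lt(fit$training_record$train_mse, 1e-3)
})

test_that("fitting is reproducible and validates its inputs", {
  set.seed(3)
  X <- matrix(runif(20 * 27), 20, 27)
  y <- X[, 1] + 0.5
  tr <- list(features = X, targets = y)
  f1 <- fit_mlp(tr, tr, node_range = 1:3, restarts = 2, seed = 9)
  f2 <- fit_mlp(tr, tr, node_range = 1:3, restarts = 2, seed = 9)
  expect_identical(coef(f1), coef(f2))
  expect_error(fit_mlp(tr, list(features = X[0, , drop = FALSE],
                                targets = numeric(0))), "empty")
  bad <- tr
  bad$targets[3] <- -Inf
  rownames(bad$features) <- paste0("exp", 1:20)
  expect_error(fit_mlp(bad, tr), "exp3")
})

test_that("the champion has minimal validation cost among all candidates", {
  set.seed(4)
  X <- matrix(runif(30 * 27), 30, 27)
  y <- 2 * X[, 3] - X[, 5] + 1
  Xv <- matrix(runif(10 * 27), 10, 27)
  yv <- 2 * Xv[, 3] - Xv[, 5] + 1
  fit <- fit_mlp(list(features = X, targets = y),
                 list(features = Xv, targets = yv),
                 node_range = 1:4, restarts = 10, seed = 5)
  rec <- fit$training_record
  expect_equal(rec$validation_mse, min(rec$candidate_validation_mse))
})

test_that("nM predictions are the log-space predictions through 10^x", {
  m <- make_mlp(matrix(0, 1, 27), 0, 0, 2)   # constant log10 output of 2
  X <- matrix(runif(5 * 27), 5, 27)
  expect_equal(predict(m, X, type = "nM"), rep(100, 5))
  m0 <- make_mlp(matrix(0, 1, 27), 0, 0, 0)
  expect_equal(predict(m0, X, type = "nM"), rep(1, 5))
  # round trip for an arbitrary fitted model
  set.seed(6)
  Xf <- matrix(runif(15 * 27), 15, 27)
  fit <- fit_mlp(list(features = Xf, targets = Xf[, 1]),
                 list(features = Xf, targets = Xf[, 1]),
                 node_range = 2, restarts = 2, seed = 1)
  expect_equal(predict(fit, Xf, type = "nM"),
               10^predict(fit, Xf, type = "log10"))
})

test_that("magnitude predictions are monotone in dose on noiseless fixtures", {
  # train on the analytic generator magnitudes (no noise) and probe the
  # fitted surface along each agonist dose channel
  d <- build_design_matrix()
  p0 <- generator_params(noise_sd = 0)
  mags <- vapply(seq_len(nrow(d)), function(i) {
    y <- platecal:::curve_family(0:540, d[i, ], p0)
    max(y) - min(y)
  }, 0)
  keep <- mags > 1e-6
  X <- expand_features(scale_conditions(d))[keep, ]
  y <- log10(mags[keep])
  fit <- fit_mlp(list(features = X, targets = y),
                 list(features = X, targets = y),
                 node_range = 4:6, restarts = 10, seed = 3)
  for (ag in c("collagen", "crp", "thrombin")) {
    # interior of the training hull (the quadratic features let the
    # surface bend down again beyond the last training dose, so the
    # property is asserted over the rising low-to-mid dose range the OAT
    # sweep probes)
    fr <- seq(0.05, 0.5, by = 0.05)
    grid <- do.call(rbind, lapply(fr, function(f) {
      row <- d[d$agonist == ag, ][1, ]
      row$dose <- f * default_design_spec()$max_doses[[ag]]
      expand_features(scale_conditions(row))
    }))
    pred <- predict(fit, grid, type = "log10")
    expect_gt(min(diff(pred)), -0.05)  # flat rectifier-region tolerance
    expect_gt(pred[length(fr)] - pred[1], 0.2)
  }
})
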