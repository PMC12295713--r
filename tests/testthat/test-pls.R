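planted_X <- function(n = 40, p = 6, seed = 8) {
  set.seed(seed)
  X <- matrix(runif(n * p, 0, 2), n, p)
  colnames(X) <- c("col", "crp", "thr", "egta", "ai", "thap")[1:p]
  X
}

orthogonal_X <- function(n = 40, p = 6, seed = 8) {
  set.seed(seed)
  M <- scale(matrix(rnorm(n * p), n, p), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(M)) %*% diag(c(1, 2, 0.5, 1.5, 0.8, 1.2)[1:p])
  colnames(Q) <- c("col", "crp", "thr", "egta", "ai", "thap")[1:p]
  Q
}

test_that("a planted noiseless linear response is recovered exactly", {
  # two latent directions suffice when the design columns are orthogonal
  # (the planted coefficient vector then lies in the 2-dimensional Krylov
  # space the first two PLS components span)
  X <- orthogonal_X()
  y <- 2 * X[, 1] - X[, 2]
  m <- fit_pls(X, y, n_components = 2)
  pred <- predict(m, X)
  expect_equal(r2_score(y, pred), 1, tolerance = 1e-8)
  expect_lt(max(abs(pred - y)), 1e-6)
  # variable with zero coefficient gets (near-)zero loading weight
  expect_lt(max(abs(pls_loadings(m)[c("egta", "ai", "thap"), ])), 1e-8)
})

test_that("full-component PLS equals ordinary least squares on full-rank data", {
  X <- planted_X(n = 30)
  set.seed(9)
  y <- X %*% c(1, -0.5, 0.3, 2, 0, -1) + rnorm(30, sd = 0.3)
  m <- fit_pls(X, drop(y), n_components = 6)
  ols <- lm(y ~ X)
  expect_equal(unname(predict(m, X)), unname(fitted(ols)),
               tolerance = 1e-8)
  expect_equal(unname(coef(m)), unname(coef(ols)[-1]), tolerance = 1e-6)
})

test_that("scores are orthogonal and explained variance does not increase", {
  X <- planted_X(n = 50)
  set.seed(10)
  y <- drop(X %*% c(1, 1, -2, 0.5, 0.1, 0)) + rnorm(50, sd = 0.5)
  m <- fit_pls(X, y, n_components = 4)
  G <- crossprod(m$scores)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)
  expect_true(all(diff(m$explained_variance) <= 1e-8))
})

test_that("prediction centering and permutation identities hold", {
  X <- planted_X(n = 25)
  y <- drop(X %*% c(0.5, 1, 0, -1, 0.2, 0.8))
  m <- fit_pls(X, y, 3)
  expect_equal(unname(predict(m, matrix(colMeans(X), 1))), mean(y))
  idx <- sample(nrow(X))
  expect_equal(predict(m, X[idx, ]), predict(m, X)[idx])
  expect_error(predict(m, X[, 1:3]), "arity")
})

test_that("loading weights are invariant to duplicating every observation", {
  X <- planted_X(n = 20)
  y <- drop(X %*% c(1, 0, 0, -2, 0, 1))
  m1 <- fit_pls(X, y, 2)
  m2 <- fit_pls(rbind(X, X), c(y, y), 2)
  expect_equal(pls_loadings(m1), pls_loadings(m2), tolerance = 1e-10)
})

test_that("degenerate inputs are rejected", {
  X <- planted_X(n = 15)
  y <- drop(X %*% c(1, 0, 0, 0, 0, 0))
  expect_error(fit_pls(X, y, 0), "n_components")
  expect_error(fit_pls(X, y, 7), "n_components")
  expect_error(fit_pls(X, rep(1, 15), 2), "constant")
  m <- fit_pls(X, y, 2)
  expect_error(pls_loadings(m, 1:3), "components")
})

test_that("generator-based magnitude loadings show the entry-block sign pattern", {
  # noiseless magnitudes over the full design: EGTA lowers them (negative
  # loading), thapsigargin raises them (positive loading)
  d <- build_design_matrix()
  p0 <- generator_params(noise_sd = 0)
  mag <- vapply(seq_len(nrow(d)), function(i) {
    y <- platecal:::curve_family(0:540, d[i, ], p0)
    max(y) - min(y)
  }, 0)
  keep <- mag > 1e-6
  X <- as.matrix(scale_conditions(d)[keep, c("col", "crp", "thr", "egta",
                                             "ai", "thap")])
  m <- fit_pls(X, log10(mag[keep]), 2)
  L <- pls_loadings(m)
  expect_lt(L["egta", 1], 0)
  expect_gt(L["thap", 1], 0)
})

test_that("a drug acting as an entry blocker loads with EGTA in the drug-augmented model", {
  dd <- build_design_matrix(include_drug_block = TRUE)
  curves <- generate_dataset(dd, generator_params(), seed = 202)
  prep <- preprocess_curves(curves)
  feats <- scalar_feature_table(prep$uniform)
  X <- as.matrix(scale_conditions(dd, include_drug = TRUE)[,
         c("col", "crp", "thr", "egta", "ai", "thap", "drug")])
  res <- drug_augmented_pls(X[, -5], feats)   # AI column is constant 0 here
  rep_mag <- res$report[res$report$characteristic == "magnitude", ]
  d_egta <- rep_mag$distance_to_drug[rep_mag$variable == "egta"]
  d_thap <- rep_mag$distance_to_drug[rep_mag$variable == "thap"]
  expect_lt(d_egta, d_thap)
  expect_error(drug_augmented_pls(X[X[, "drug"] == 0, -5], feats[dd$drug == 0, ]),
               "constant")
})

test_that("a drug with no effect gets a vanishing loading", {
  # duplicate the design with and without the drug, leaving the response
  # untouched: the drug column is then exactly orthogonal to the response
  X6 <- planted_X(n = 16)
  y6 <- drop(X6 %*% c(1, -1, 0.5, 2, 0, -0.5))
  X <- rbind(cbind(X6, drug = 0), cbind(X6, drug = 1))
  m <- fit_pls(X, c(y6, y6), 2)
  expect_lt(max(abs(pls_loadings(m)["drug", ])), 1e-8)
})
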