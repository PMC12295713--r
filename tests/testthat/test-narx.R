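test_that("lag vectors read the output history with zero pre-history", {
  expect_equal(lag_vector(numeric(0), 0), rep(0, 8))
  h <- c(0, 0.5)                       # y(0) = 0, y(1) = 0.5
  lv <- lag_vector(h, 2)
  expect_equal(lv[1], 0.5)             # 1 s before t = 2
  expect_equal(lv[-1], rep(0, 7))
  const <- rep(0.3, 41)
  expect_equal(lag_vector(const, 40), rep(0.3, 8))
})

test_that("closed-loop simulation equals the brute-force recursion to 1e-12", {
  for (seed in 1:4) {
    m <- random_small_narx(arch = c(3, 4, 2), seed = seed)
    x <- runif(27, 0, 1)
    sim <- narx_simulate(m, x, horizon = 120)
    oracle <- oracle_narx_recursion(m, x, 120)
    expect_lt(max(abs(sim - oracle)), 1e-12)
  }
  # batched simulation agrees with per-condition simulation
  m <- random_small_narx(seed = 9)
  X <- matrix(runif(3 * 27), 3, 27)
  batch <- narx_simulate(m, X, horizon = 80)
  for (i in 1:3) {
    expect_equal(batch[i, ], narx_simulate(m, X[i, ], horizon = 80))
  }
})

test_that("degenerate parameter sets behave as the recurrence dictates", {
  m <- random_small_narx(seed = 1)
  m$W[] <- 0; m$H1[] <- 0; m$L2[] <- 0; m$H2[] <- 0; m$L3[] <- 0
  m$H3[] <- 0; m$L4[] <- 0; m$b1[] <- 0; m$b2[] <- 0; m$b3[] <- 0; m$b4 <- 0
  expect_equal(narx_simulate(m, runif(27), 50), rep(0, 50))
  expect_length(narx_simulate(random_small_narx(seed = 2), runif(27), 541),
                541)
})

test_that("the BPTT gradient matches central finite differences", {
  m <- random_small_narx(arch = c(2, 3, 2), seed = 5)
  skel <- m
  X <- matrix(runif(2 * 27), 2, 27)
  TGT <- matrix(runif(2 * 60), 2, 60)
  EXT <- array(0, c(2, 8, 60))
  p <- platecal:::narx_pack(m)
  obj <- function(pp) platecal:::narx_rollout_obj(pp, skel, X, EXT, TGT)
  g <- obj(p)$gradient
  idx <- round(seq(1, length(p), length.out = 25))
  for (k in idx) {
    e <- rep(0, length(p)); e[k] <- 1e-6
    num <- (obj(p + e)$value - obj(p - e)$value) / 2e-6
    expect_equal(g[k], num, tolerance = 1e-5)
  }
})

test_that("training is reproducible and validates architecture and inputs", {
  set.seed(21)
  gen <- random_small_narx(seed = 31)
  X <- matrix(runif(6 * 27), 6, 27)
  TGT <- narx_simulate(gen, X, 100)
  tr <- list(features = X, targets = TGT)
  f1 <- fit_narx(tr, c(2, 3, 2), restarts = 1, seed = 4, maxit_sp = 20,
                 maxit_seg = 0, maxit_cl = 10)
  f2 <- fit_narx(tr, c(2, 3, 2), restarts = 1, seed = 4, maxit_sp = 20,
                 maxit_seg = 0, maxit_cl = 10)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$L4, f2$L4)
  expect_error(fit_narx(list(features = NULL), c(2, 2, 2)), "empty")
  expect_error(fit_narx(tr, c(1, 3, 2)), "between 2 and 20")
  expect_error(fit_narx(tr, c(2, 3)), "between 2 and 20")
})

test_that("a planted trend network is recovered to high held-out fidelity", {
  set.seed(77)
  gen <- random_small_narx(arch = c(3, 3, 2), seed = 13, scale = 0.8)
  gen$b4 <- 0.3
  X <- matrix(runif(24 * 27, 0, 1), 24, 27)
  Y <- narx_simulate(gen, X, 200)
  expect_gt(diff(range(Y)), 0.05)     # non-trivial planted dynamics
  tr <- list(features = X[1:19, ], targets = Y[1:19, ])
  fit <- fit_narx(tr, c(3, 3, 2), restarts = 2, seed = 3,
                  maxit_sp = 80, maxit_seg = 120, maxit_cl = 150,
                  seg_len = 41)
  held <- vapply(20:24, function(i)
    r2_score(Y[i, ], narx_simulate(fit, X[i, ], 200)), 0)
  expect_gt(mean(held), 0.95)
})

test_that("architecture search samples the 19^3 grid deterministically", {
  gen <- random_small_narx(seed = 41)
  X <- matrix(runif(5 * 27), 5, 27)
  TGT <- narx_simulate(gen, X, 80)
  tr <- list(features = X[1:4, ], targets = TGT[1:4, ])
  va <- list(features = X[5, , drop = FALSE],
             targets = TGT[5, , drop = FALSE])
  cheap <- list(sp = 10, seg = 0, cl = 0)
  s1 <- search_narx(tr, va, budget = 3, restarts = 1, seed = 2,
                    search_maxit = cheap, final_maxit = cheap)
  s2 <- search_narx(tr, va, budget = 3, restarts = 1, seed = 2,
                    search_maxit = cheap, final_maxit = cheap)
  expect_identical(s1$search_table[, 1:3], s2$search_table[, 1:3])
  expect_equal(nrow(s1$search_table), 3)
  expect_true(all(s1$search_table[, 1:3] >= 2 & s1$search_table[, 1:3] <= 20))
  s3 <- search_narx(tr, va, budget = 1, restarts = 1, seed = 7,
                    search_maxit = cheap, final_maxit = cheap)
  expect_equal(nrow(s3$search_table), 1)
})
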