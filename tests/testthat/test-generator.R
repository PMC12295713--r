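test_that("Hill dose-response has the closed-form landmarks", {
  expect_equal(dose_response(0, ec50 = 2, hill = 1.5), 0)
  expect_equal(dose_response(2, ec50 = 2, hill = 1.5), 0.5)
  expect_gt(dose_response(1000 * 2, ec50 = 2, hill = 1), 0.999)
  expect_error(dose_response(-1, 2, 1), "negative")
  # monotone in dose
  doses <- seq(0, 50, by = 0.5)
  expect_true(all(diff(dose_response(doses, 5, 1.7)) >= 0))
})

test_that("noiseless vehicle curves are flat and thrombin curves transient", {
  d <- build_design_matrix()
  p0 <- generator_params(noise_sd = 0)
  veh <- generate_curve(d[1, ], p0)   # vehicle control, no inhibitors
  expect_equal(diff(range(veh$values)), 0)
  thr <- d[d$agonist == "thrombin" & d$dose == 10 &
             d$egta == 0 & d$ai == 0 & d$thap == 0, ][1, ]
  cv <- generate_curve(thr, p0)
  sm <- smooth_curve(resample(cv))
  f <- compute_scalar_features(sm)
  expect_lt(f$ylast, 1)               # decays below its own maximum
  expect_lt(f$tmax, 0.5)              # early peak
})

test_that("curve generation is deterministic given the seed", {
  d <- build_design_matrix()
  c1 <- generate_curve(d[50, ], generator_params(), seed = 7)
  c2 <- generate_curve(d[50, ], generator_params(), seed = 7)
  expect_identical(c1$values, c2$values)
  c3 <- generate_curve(d[50, ], generator_params(), seed = 8)
  expect_false(identical(c1$values, c3$values))
})

test_that("dataset generation yields one curve per condition at the raw sampling rates", {
  d <- build_design_matrix()
  curves <- generate_dataset(d, generator_params(), seed = 1)
  expect_length(curves, 72)
  thr_id <- as.character(d$exp_id[d$agonist == "thrombin"][1])
  col_id <- as.character(d$exp_id[d$agonist == "collagen"][1])
  expect_length(curves[[thr_id]]$times, 271)   # 0..540 step 2
  expect_length(curves[[col_id]]$times, 136)   # 0..540 step 4
  expect_true(all(vapply(curves, function(cv) min(cv$values) >= 0, TRUE)))
  d2 <- rbind(d, d[1, ])
  expect_error(generate_dataset(d2, generator_params(), 1), "duplicate")
})

test_that("noiseless effect directions hold: dose response, EGTA lowering, thapsigargin sustain", {
  d <- build_design_matrix()
  p0 <- generator_params(noise_sd = 0)
  mag <- function(row) {
    cv <- generate_curve(row, p0)
    diff(range(cv$values))
  }
  # magnitude non-decreasing in dose (collagen, no inhibitors)
  rows <- d[d$agonist == "collagen" & d$egta == 0 & d$ai == 0 & d$thap == 0, ]
  mags <- vapply(seq_len(nrow(rows)), function(i) mag(rows[i, ]), 0)
  expect_true(all(diff(mags[order(rows$dose)]) >= 0))
  # EGTA never increases the magnitude at matched conditions
  for (id in c(15, 44, 61)) {
    row <- d[id, ]
    row_e <- row; row_e$egta <- 1
    expect_lte(mag(row_e), mag(row))
  }
  # thapsigargin + CaCl2 gives a monotone, sustained curve
  thap <- d[d$agonist == "thrombin" & d$dose == 10 & d$thap == 1 &
              d$egta == 0, ][1, ]
  sm <- smooth_curve(resample(generate_curve(thap, p0)))
  f <- compute_scalar_features(sm)
  expect_equal(f$ylast, 1, tolerance = 1e-6)
  # monotone non-decreasing up to smoothing ripple (< 1% of the range)
  v <- sm$values
  expect_lt(max(cummax(v) - v), 0.01 * diff(range(v)))
})

test_that("scalar features of noiseless curves match the analytic curve family", {
  d <- build_design_matrix()
  p0 <- generator_params(noise_sd = 0)
  for (id in c(20, 44, 63)) {
    row <- d[id, ]
    cv <- generate_curve(row, p0)
    f <- compute_scalar_features(smooth_curve(resample(cv)))
    # oracle: evaluate the closed-form family directly on the 1 s grid
    y <- platecal:::curve_family(0:540, row, p0)
    o_mag <- max(y) - min(y)
    o_tmax <- (which.max(y) - 1) / 540
    o_ylast <- (y[541] - min(y)) / o_mag
    expect_equal(f$magnitude, o_mag, tolerance = 0.02)
    expect_equal(f$tmax, o_tmax, tolerance = 0.02)
    expect_equal(f$ylast, o_ylast, tolerance = 0.02)
  }
})
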