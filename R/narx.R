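#' @useDynLib platecal, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Default feedback-delay taps of the trend network (seconds before now)
#' @export
default_delays <- function() c(1L, 3L, 6L, 10L, 15L, 21L, 28L, 36L)

#' Feedback-delay vector
#'
#' Values of the output `d` seconds before the current step, for each delay
#' tap; times before the record start are 0 (the platelet is assumed to be
#' in a pre-stimulation steady state).
#'
#' @param history Output values so far, `history[i]` being the value at
#'   time `i - 1` seconds.
#' @param t Current time step (seconds, 0-based).
#' @param delays Integer delay taps.
#' @return Numeric vector of `length(delays)` lagged outputs.
#' @export
lag_vector <- function(history, t, delays = default_delays()) {
  idx <- t - delays + 1L        # position of time t-d in the history
  out <- numeric(length(delays))
  ok <- idx >= 1L
  out[ok] <- history[idx[ok]]
  out
}

# random NARX parameter set for a given architecture, fan-in scaled
narx_init <- function(arch, n_in = 27L, delays = default_delays()) {
  nd <- length(delays)
  ru <- function(r, c) matrix(stats::runif(r * c, -0.5, 0.5) / sqrt(c), r, c)
  list(W = ru(arch[1], n_in), H1 = ru(arch[1], nd),
       L2 = ru(arch[2], arch[1]), H2 = ru(arch[2], nd),
       L3 = ru(arch[3], arch[2]), H3 = ru(arch[3], nd),
       L4 = stats::runif(arch[3], -0.5, 0.5) / sqrt(arch[3]),
       b1 = numeric(arch[1]), b2 = numeric(arch[2]),
       b3 = numeric(arch[3]), b4 = 0,
       arch = arch, delays = delays, n_in = n_in)
}

narx_n_params <- function(arch, n_in = 27L, nd = 8L) {
  arch[1] * (n_in + nd + 1) + arch[2] * (arch[1] + nd + 1) +
    arch[3] * (arch[2] + nd + 1) + arch[3] + 1
}

narx_pack <- function(m) {
  c(as.vector(m$W), as.vector(m$H1), as.vector(m$L2), as.vector(m$H2),
    as.vector(m$L3), as.vector(m$H3), m$L4, m$b1, m$b2, m$b3, m$b4)
}

narx_unpack <- function(p, skel) {
  a <- skel$arch; n_in <- skel$n_in; nd <- length(skel$delays)
  pos <- 0L
  take <- function(n) {
    v <- p[pos + seq_len(n)]
    pos <<- pos + n
    v
  }
  list(W = matrix(take(a[1] * n_in), a[1], n_in),
       H1 = matrix(take(a[1] * nd), a[1], nd),
       L2 = matrix(take(a[2] * a[1]), a[2], a[1]),
       H2 = matrix(take(a[2] * nd), a[2], nd),
       L3 = matrix(take(a[3] * a[2]), a[3], a[2]),
       H3 = matrix(take(a[3] * nd), a[3], nd),
       L4 = take(a[3]), b1 = take(a[1]), b2 = take(a[2]),
       b3 = take(a[3]), b4 = take(1),
       arch = a, delays = skel$delays, n_in = n_in)
}

narx_model_part <- function(x) {
  x[c("W", "H1", "L2", "H2", "L3", "H3", "L4", "b1", "b2", "b3", "b4",
      "arch", "delays", "n_in")]
}

#' Closed-loop simulation of the trend network
#'
#' Runs the recurrent network forward for `horizon` one-second steps. At
#' each step the delayed model outputs (taps at 1, 3, 6, 10, 15, 21, 28 and
#' 36 s by default, zero before the record starts) feed all three
#' tanh-activated hidden layers together with the constant 27-feature
#' exogenous input; the output layer is linear.
#'
#' @param model A `"ca_narx"` model (or bare parameter list).
#' @param features 27-vector, or a matrix with one row per condition (all
#'   conditions are simulated in parallel).
#' @param horizon Number of 1 s steps (default 541, i.e. 0-540 s).
#' @return Numeric vector (single condition) or matrix (conditions x time)
#'   of predicted scaled values.
#' @export
narx_simulate <- function(model, features, horizon = 541L) {
  single <- !is.matrix(features)
  X <- if (single) matrix(features, nrow = 1) else features
  if (ncol(X) != model$n_in) stop("feature arity mismatch")
  Y <- narx_sim_cpp(model$W, model$H1, model$L2, model$H2, model$L3,
                    model$H3, model$L4, model$b1, model$b2, model$b3,
                    model$b4, X, as.integer(horizon),
                    as.integer(model$delays))
  if (any(!is.finite(Y))) stop("non-finite values in NARX simulation")
  if (single) drop(Y) else Y
}

# ---- series-parallel (open-loop) training -------------------------------
# With teacher forcing the lag taps read the *target* curve, so the network
# collapses to a feedforward map (y_h, I) -> y trained on all time steps at
# once.

narx_openloop_data <- function(features, targets, delays, stride = 1L) {
  K <- nrow(targets); horizon <- ncol(targets); nd <- length(delays)
  tt <- seq(1L, horizon, by = stride)
  N <- K * length(tt)
  Yh <- matrix(0, N, nd)
  Xf <- matrix(0, N, ncol(features))
  y <- numeric(N)
  row <- 0L
  for (t in tt) {
    idx <- t - delays
    ok <- idx >= 1L
    block <- row + seq_len(K)
    if (any(ok)) Yh[block, ok] <- targets[, idx[ok], drop = FALSE]
    Xf[block, ] <- features
    y[block] <- targets[, t]
    row <- row + K
  }
  list(Yh = Yh, Xf = Xf, y = y)
}

# loss and analytic gradient of the open-loop MSE; used by optim L-BFGS
narx_openloop_obj <- function(p, skel, Yh, Xf, y) {
  m <- narx_unpack(p, skel)
  N <- length(y)
  A1 <- tanh(sweep(Yh %*% t(m$H1) + Xf %*% t(m$W), 2, m$b1, `+`))
  A2 <- tanh(sweep(A1 %*% t(m$L2) + Yh %*% t(m$H2), 2, m$b2, `+`))
  A3 <- tanh(sweep(A2 %*% t(m$L3) + Yh %*% t(m$H3), 2, m$b3, `+`))
  yhat <- drop(A3 %*% m$L4) + m$b4
  r <- yhat - y
  g <- 2 * r / N
  d3 <- (g %o% m$L4) * (1 - A3^2)
  d2 <- (d3 %*% m$L3) * (1 - A2^2)
  d1 <- (d2 %*% m$L2) * (1 - A1^2)
  grad <- c(as.vector(crossprod(d1, Xf)),   # W
            as.vector(crossprod(d1, Yh)),   # H1
            as.vector(crossprod(d2, A1)),   # L2
            as.vector(crossprod(d2, Yh)),   # H2
            as.vector(crossprod(d3, A2)),   # L3
            as.vector(crossprod(d3, Yh)),   # H3
            drop(crossprod(A3, g)),         # L4
            colSums(d1), colSums(d2), colSums(d3), sum(g))
  list(value = mean(r^2), gradient = grad)
}

# ---- rollout training (truncated segments and full closed loop) ---------
# EXT holds the lag values that fall outside the simulated window: zeros
# for a full closed-loop rollout from rest, target history for
# teacher-initialised segments.

narx_segment_data <- function(features, targets, delays,
                              seg_len = 61L, by = 60L) {
  K <- nrow(targets); horizon <- ncol(targets); nd <- length(delays)
  starts <- seq(1L, horizon - seg_len + 1L, by = by)
  n <- K * length(starts)
  EXT <- array(0, c(n, nd, seg_len))
  TGT <- matrix(0, n, seg_len)
  for (si in seq_along(starts)) {
    g0 <- starts[si]
    block <- (si - 1L) * K + seq_len(K)
    for (j in seq_len(seg_len)) {
      g <- g0 + j - 1L
      TGT[block, j] <- targets[, g]
      for (k in seq_len(nd)) {
        gs <- g - delays[k]
        if (j - delays[k] < 1L && gs >= 1L) {
          EXT[block, k, j] <- targets[, gs]
        }
      }
    }
  }
  list(EXT = EXT, TGT = TGT,
       X = features[rep(seq_len(K), length(starts)), , drop = FALSE])
}

narx_rollout_obj <- function(p, skel, X, EXT, TGT) {
  m <- narx_unpack(p, skel)
  res <- narx_obj_cpp(m$W, m$H1, m$L2, m$H2, m$L3, m$H3, m$L4,
                      m$b1, m$b2, m$b3, m$b4, X, EXT, TGT,
                      as.integer(m$delays), TRUE)
  list(value = res$value,
       gradient = c(as.vector(res$gW), as.vector(res$gH1),
                    as.vector(res$gL2), as.vector(res$gH2),
                    as.vector(res$gL3), as.vector(res$gH3),
                    res$gL4, res$gb1, res$gb2, res$gb3, res$gb4))
}

# run optim::L-BFGS-B on an objective returning value+gradient, caching the
# forward pass between paired fn/gr calls
run_lbfgs <- function(p0, obj, maxit, ...) {
  if (maxit <= 0) return(list(par = p0))
  cache <- new.env()
  eval_at <- function(p) {
    if (!is.null(cache$p) && identical(cache$p, p)) return(cache$res)
    res <- obj(p, ...)
    cache$p <- p; cache$res <- res
    res
  }
  stats::optim(p0, fn = function(p) eval_at(p)$value,
               gr = function(p) eval_at(p)$gradient,
               method = "L-BFGS-B",
               control = list(maxit = maxit))
}

#' Fit the trend network for one architecture
#'
#' Trains the closed-loop NARX network on scaled 541-point curves by
#' minimising the mean squared simulation error, with multiple random
#' restarts. The default mode warm-starts in series-parallel (open-loop)
#' form -- teacher forcing feeds the lagged *target* values, reducing the
#' recurrence to a feedforward least-squares problem -- then tightens the
#' warm start on teacher-initialised 61 s rollout segments, and finally
#' fine-tunes the full closed loop with a backpropagation-through-time
#' gradient. Restarts whose cost diverges are discarded (and recorded).
#'
#' @param train List with `features` (matrix, curves x 27) and `targets`
#'   (matrix, curves x 541 scaled values).
#' @param architecture Integer vector of three hidden-layer sizes, each in
#'   2-20.
#' @param restarts Random restarts (default 5).
#' @param seed Integer seed.
#' @param mode `"sp+cl"` (default: staged warm start, then closed loop),
#'   `"sp"` (series-parallel only) or `"cl"` (closed-loop only).
#' @param maxit_sp,maxit_seg,maxit_cl Optimiser iteration caps for the
#'   teacher-forcing, segment-rollout and closed-loop phases.
#' @param stride Time-step stride for the teacher-forcing phase.
#' @param seg_len Segment length (s) of the intermediate rollout phase.
#' @param delays Feedback taps, seconds.
#' @return Object of class `"ca_narx"`.
#' @export
fit_narx <- function(train, architecture, restarts = 5, seed = 1L,
                     mode = c("sp+cl", "sp", "cl"),
                     maxit_sp = 100, maxit_seg = 150, maxit_cl = 150,
                     stride = 2L, seg_len = 61L,
                     delays = default_delays()) {
  mode <- match.arg(mode)
  if (is.null(train$features) || nrow(train$features) == 0) {
    stop("empty training set")
  }
  if (length(architecture) != 3 ||
      any(architecture < 2) || any(architecture > 20)) {
    stop("architecture must be three layer sizes between 2 and 20")
  }
  stopifnot(nrow(train$features) == nrow(train$targets),
            ncol(train$targets) >= max(delays) + 1)
  horizon <- ncol(train$targets)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ol <- if (mode != "cl" && maxit_sp > 0) {
    narx_openloop_data(train$features, train$targets, delays, stride)
  }
  sg <- if (mode == "sp+cl" && maxit_seg > 0) {
    narx_segment_data(train$features, train$targets, delays, seg_len)
  }
  EXT0 <- array(0, c(nrow(train$features), length(delays), horizon))
  best <- NULL; best_cost <- Inf; diverged <- 0L
  for (r in seq_len(restarts)) {
    m0 <- narx_init(architecture, ncol(train$features), delays)
    skel <- m0
    p <- narx_pack(m0)
    if (!is.null(ol)) {
      p <- run_lbfgs(p, narx_openloop_obj, maxit_sp, skel = skel,
                     Yh = ol$Yh, Xf = ol$Xf, y = ol$y)$par
    }
    if (!is.null(sg)) {
      p <- run_lbfgs(p, narx_rollout_obj, maxit_seg, skel = skel,
                     X = sg$X, EXT = sg$EXT, TGT = sg$TGT)$par
    }
    if (mode != "sp" && maxit_cl > 0) {
      p <- run_lbfgs(p, narx_rollout_obj, maxit_cl, skel = skel,
                     X = train$features, EXT = EXT0,
                     TGT = train$targets)$par
    }
    m <- narx_model_part(narx_unpack(p, skel))
    sim <- try(narx_simulate(m, train$features, horizon), silent = TRUE)
    if (inherits(sim, "try-error")) {
      diverged <- diverged + 1L
      next
    }
    cost <- mean((sim - train$targets)^2)
    if (!is.finite(cost)) {
      diverged <- diverged + 1L
      next
    }
    if (cost < best_cost) {
      best_cost <- cost
      best <- c(m, list(restart = r))
    }
  }
  if (is.null(best)) stop("all restarts diverged")
  out <- c(best, list(mode = mode,
                      training_record = list(
                        seed = seed, restarts = restarts,
                        restart = best$restart, train_mse = best_cost,
                        diverged = diverged)))
  class(out) <- "ca_narx"
  out
}

#' Randomised architecture search for the trend network
#'
#' Samples architectures without replacement from the 19 x 19 x 19 grid
#' (layer sizes 2-20, 6859 candidates), trains each with `restarts` cheap
#' warm-started restarts, and selects by mean closed-loop trend R-squared
#' on the validation curves (ties broken towards fewer parameters). The
#' winning architecture is then retrained at full depth.
#'
#' @param train,validation Lists with `features` and `targets` matrices.
#' @param budget Number of architectures to try (clamped to the grid size
#'   with a warning).
#' @param restarts Restarts per architecture during the screening phase.
#' @param seed Integer seed.
#' @param search_maxit Named list of iteration caps (`sp`, `seg`, `cl`)
#'   for the search phase; the default screens with the staged warm start
#'   only.
#' @param final_maxit Iteration caps for the final retraining of the
#'   selected architecture.
#' @param final_restarts Restarts for the final retraining.
#' @param ensemble Number of best-by-validation final restarts whose
#'   simulated trends are combined point-wise by their median (default
#'   all; 1 returns the single best-by-validation network). The median
#'   over restarts suppresses the occasional rollout that settles on a
#'   wrong asymptote for a held-out condition.
#' @param stride,seg_len Passed to [fit_narx()].
#' @return List with `model` (a `"ca_narx_ensemble"`, or a `"ca_narx"`
#'   when `ensemble = 1`), `architecture`, `validation_r2` and the full
#'   `search_table`.
#' @export
search_narx <- function(train, validation, budget = 30, restarts = 5,
                        seed = 1L,
                        search_maxit = list(sp = 60, seg = 60, cl = 0),
                        final_maxit = list(sp = 100, seg = 200, cl = 600),
                        final_restarts = 8, ensemble = final_restarts,
                        stride = 2L, seg_len = 61L) {
  stopifnot(budget >= 1)
  grid <- as.matrix(expand.grid(n1 = 2:20, n2 = 2:20, n3 = 2:20))
  if (budget > nrow(grid)) {
    warning("budget exceeds the ", nrow(grid), "-architecture grid; clamped")
    budget <- nrow(grid)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cand_idx <- sample.int(nrow(grid), budget)
  fit_seeds <- sample.int(.Machine$integer.max, budget + 1L)
  r2s <- numeric(budget); npar <- numeric(budget)
  for (i in seq_len(budget)) {
    arch <- grid[cand_idx[i], ]
    m <- fit_narx(train, arch, restarts = restarts, seed = fit_seeds[i],
                  mode = "sp+cl", maxit_sp = search_maxit$sp,
                  maxit_seg = search_maxit$seg, maxit_cl = search_maxit$cl,
                  stride = stride, seg_len = seg_len)
    r2s[i] <- mean_trend_r2(m, validation$features, validation$targets)
    npar[i] <- narx_n_params(arch)
  }
  best <- order(-r2s, npar, seq_len(budget))[1]
  best_arch <- grid[cand_idx[best], ]
  # retrain the winning architecture at full depth; restarts are again
  # ranked by validation trend R^2
  members <- vector("list", final_restarts)
  member_r2 <- numeric(final_restarts)
  for (r in seq_len(final_restarts)) {
    mr <- fit_narx(train, best_arch, restarts = 1,
                   seed = fit_seeds[budget + 1L] %% 1000000L + r,
                   mode = "sp+cl",
                   maxit_sp = final_maxit$sp, maxit_seg = final_maxit$seg,
                   maxit_cl = final_maxit$cl, stride = stride,
                   seg_len = seg_len)
    members[[r]] <- mr
    member_r2[r] <- mean_trend_r2(mr, validation$features,
                                  validation$targets)
  }
  ord <- order(-member_r2)
  model <- if (ensemble > 1) {
    structure(list(members = members[ord[seq_len(min(ensemble,
                                                     final_restarts))]],
                   member_validation_r2 = member_r2[ord],
                   arch = best_arch, delays = members[[1]]$delays,
                   n_in = members[[1]]$n_in),
              class = "ca_narx_ensemble")
  } else {
    members[[ord[1]]]
  }
  search_table <- data.frame(
    n1 = grid[cand_idx, 1], n2 = grid[cand_idx, 2], n3 = grid[cand_idx, 3],
    n_params = npar, validation_r2 = r2s)
  list(model = model, architecture = unname(best_arch),
       validation_r2 = mean_trend_r2(model, validation$features,
                                     validation$targets),
       search_table = search_table)
}

# mean per-curve R^2 of closed-loop simulations against scaled targets
mean_trend_r2 <- function(model, features, targets) {
  sim <- try(predict(model, features, horizon = ncol(targets)),
             silent = TRUE)
  if (inherits(sim, "try-error")) return(-Inf)
  mean(vapply(seq_len(nrow(targets)), function(i)
    r2_score(targets[i, ], sim[i, ]), 0))
}

#' Per-curve trend R-squared of a fitted trend network
#'
#' @param model A `"ca_narx"` or `"ca_narx_ensemble"`.
#' @param features Feature matrix (curves x 27).
#' @param targets Scaled target matrix (curves x 541).
#' @return Named numeric vector of per-curve R-squared values.
#' @export
trend_r2 <- function(model, features, targets) {
  sim <- predict(model, features, horizon = ncol(targets))
  out <- vapply(seq_len(nrow(targets)), function(i)
    r2_score(targets[i, ], sim[i, ]), 0)
  names(out) <- rownames(features)
  out
}

#' Predict scaled trends from a restart ensemble
#'
#' Simulates every member network in closed loop and takes the
#' point-wise median of the simulated curves.
#'
#' @param object A `"ca_narx_ensemble"` from [search_narx()].
#' @param conditions Scaled condition data frame or 27-column feature
#'   matrix.
#' @param horizon Simulation length in 1 s steps.
#' @param ... Unused.
#' @return Matrix (conditions x time) of predicted scaled values.
#' @export
predict.ca_narx_ensemble <- function(object, conditions, horizon = 541L,
                                     ...) {
  X <- if (is.matrix(conditions)) conditions else expand_features(conditions)
  sims <- lapply(object$members, function(m) {
    out <- narx_simulate(m, X, horizon)
    if (!is.matrix(out)) out <- matrix(out, nrow = 1)
    out
  })
  arr <- simplify2array(sims)
  apply(arr, c(1, 2), stats::median)
}

# the highest-validation-R2 network of an ensemble (or the model itself)
narx_best_member <- function(x) {
  if (inherits(x, "ca_narx_ensemble")) x$members[[1]] else x
}

#' @export
print.ca_narx_ensemble <- function(x, ...) {
  cat(sprintf(paste0("Closed-loop NARX trend ensemble: %d members,",
                     " %d x %d x %d tanh nodes\n",
                     "  member validation R2: %s\n"),
              length(x$members), x$arch[1], x$arch[2], x$arch[3],
              paste(sprintf("%.2f",
                            x$member_validation_r2[seq_along(x$members)]),
                    collapse = " ")))
  invisible(x)
}

#' Predict scaled calcium trends
#'
#' @param object A fitted `"ca_narx"`.
#' @param conditions Scaled condition data frame or 27-column feature
#'   matrix.
#' @param horizon Simulation length in 1 s steps.
#' @param ... Unused.
#' @return Matrix (conditions x time) of predicted scaled values.
#' @export
predict.ca_narx <- function(object, conditions, horizon = 541L, ...) {
  X <- if (is.matrix(conditions)) conditions else expand_features(conditions)
  out <- narx_simulate(object, X, horizon)
  if (!is.matrix(out)) out <- matrix(out, nrow = 1)
  out
}

#' @export
print.ca_narx <- function(x, ...) {
  cat(sprintf(paste0("Closed-loop NARX trend network: %d x %d x %d tanh",
                     " nodes,\n  %d feedback taps (%s s), train MSE %.4g",
                     " (%s)\n"),
              x$arch[1], x$arch[2], x$arch[3], length(x$delays),
              paste(x$delays, collapse = ", "),
              x$training_record$train_mse, x$mode))
  invisible(x)
}
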