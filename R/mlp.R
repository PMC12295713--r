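#' Forward pass of the magnitude network
#'
#' Single hidden layer of rectified linear units, linear output:
#' `b2 + v . relu(W x + b1)`. The output is the predicted log10 of the
#' curve magnitude (nM range). Inputs are expected on the network's
#' internal scale; [predict.ca_mlp()] applies the stored input
#' normalisation first.
#'
#' @param model A `"ca_mlp"` model (or a bare list with `hidden_weights`,
#'   `hidden_bias`, `output_weights`, `output_bias`).
#' @param features Numeric matrix (rows = conditions, 27 columns) or a
#'   single 27-vector.
#' @return Numeric vector of predicted log10 magnitudes.
#' @export
mlp_forward <- function(model, features) {
  X <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  W <- model$hidden_weights
  if (ncol(X) != ncol(W)) stop("feature arity mismatch: expected ", ncol(W))
  Z <- X %*% t(W) + matrix(model$hidden_bias, nrow(X), nrow(W), byrow = TRUE)
  A <- pmax(Z, 0)
  drop(A %*% model$output_weights) + model$output_bias
}

mlp_unpack <- function(p, n_nodes, n_in) {
  i <- n_nodes * n_in
  list(hidden_weights = matrix(p[1:i], n_nodes, n_in),
       hidden_bias = p[i + 1:n_nodes],
       output_weights = p[i + n_nodes + 1:n_nodes],
       output_bias = p[i + 2 * n_nodes + 1])
}

# residuals and analytic Jacobian for damped least squares; the rectifier
# subgradient at the kink is taken as 0. A tiny Tikhonov tail (sqrt(ridge)
# * theta) keeps the residual count at or above the parameter count, which
# the Levenberg-Marquardt routine requires; at the default ridge it is
# numerically irrelevant to the fit.
mlp_residuals <- function(p, X, y, n_nodes, ridge = 1e-8) {
  m <- mlp_unpack(p, n_nodes, ncol(X))
  c(y - mlp_forward(m, X), sqrt(ridge) * p)
}
mlp_jacobian <- function(p, X, y, n_nodes, ridge = 1e-8) {
  n_in <- ncol(X); n <- nrow(X)
  m <- mlp_unpack(p, n_nodes, n_in)
  Z <- X %*% t(m$hidden_weights) +
    matrix(m$hidden_bias, n, n_nodes, byrow = TRUE)
  act <- Z > 0
  A <- pmax(Z, 0)
  # d residual / d theta = -d f / d theta; the W block follows the
  # column-major packing of mlp_unpack (node index fastest)
  D <- -act * matrix(m$output_weights, n, n_nodes, byrow = TRUE)
  JW <- D[, rep(seq_len(n_nodes), times = n_in), drop = FALSE] *
    X[, rep(seq_len(n_in), each = n_nodes), drop = FALSE]
  J <- cbind(JW, D, -A, -1)
  rbind(J, diag(sqrt(ridge), length(p)))
}

# min-max input normalisation to [-1, 1], fitted on the training rows
mlp_norm_fit <- function(X) {
  lo <- apply(X, 2, min)
  list(lo = lo, range = pmax(apply(X, 2, max) - lo, 1e-12))
}
mlp_norm_apply <- function(norm, X) {
  sweep(sweep(X, 2, norm$lo), 2, norm$range, `/`) * 2 - 1
}

#' Fit the magnitude network
#'
#' Trains the single-hidden-layer rectifier network on log10 curve
#' magnitudes by damped least squares (Levenberg-Marquardt). Each restart
#' draws the node count uniformly from `node_range` and fresh
#' fan-in-scaled uniform(-0.5, 0.5) initial weights; training is stopped
#' early when the validation cost has not improved for `patience`
#' consecutive optimiser chunks, and the weights with minimal validation
#' mean squared error along the trajectory are kept. The restart with
#' minimal validation MSE is the champion (ties: fewer nodes, then lower
#' restart index); with `ensemble > 1` the returned predictor averages the
#' `ensemble` best restarts in log space, which stabilises behaviour at
#' condition-space corners that a small validation set cannot police.
#' Inputs are min-max normalised to \[-1, 1\] internally (constants fitted
#' on the training rows and stored in the model).
#'
#' @param train,validation Lists with `features` (matrix, 27 columns) and
#'   `targets` (log10 nM magnitudes).
#' @param node_range Candidate hidden-node counts (default 1:10).
#' @param restarts Number of random restarts (default 100).
#' @param seed Integer seed; the fit is fully reproducible.
#' @param ensemble Number of best-by-validation restarts averaged by
#'   [predict.ca_mlp()] (1 = champion only).
#' @param chunk,max_chunks,patience Early-stopping schedule: optimiser
#'   iterations per validation check, maximum checks, and checks without
#'   improvement tolerated before stopping.
#' @return Object of class `"ca_mlp"`: champion weights, the ensemble
#'   `members`, the input normalisation, and a `training_record`.
#' @export
fit_mlp <- function(train, validation, node_range = 1:10, restarts = 100,
                    seed = 1L, ensemble = 10, chunk = 3, max_chunks = 50,
                    patience = 6) {
  check_xy <- function(s, nm) {
    if (is.null(s$features) || nrow(s$features) == 0)
      stop(nm, " set is empty")
    if (any(!is.finite(s$targets))) {
      bad <- rownames(s$features)[!is.finite(s$targets)]
      stop("non-finite log-magnitude target (flat curve?) for experiment ",
           paste(bad, collapse = ", "))
    }
  }
  check_xy(train, "training"); check_xy(validation, "validation")
  n_in <- ncol(train$features)
  norm <- mlp_norm_fit(train$features)
  Xtr <- mlp_norm_apply(norm, train$features)
  Xva <- mlp_norm_apply(norm, validation$features)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  node_draws <- sample(node_range, restarts, replace = TRUE)
  cands <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    n_nodes <- node_draws[r]
    npar <- n_nodes * n_in + 2 * n_nodes + 1
    p <- stats::runif(npar, -0.5, 0.5) / sqrt(n_in)
    va_best <- Inf; p_best <- p; rises <- 0L
    for (ch in seq_len(max_chunks)) {
      fit <- suppressWarnings(minpack.lm::nls.lm(
        par = p, fn = mlp_residuals, jac = mlp_jacobian,
        X = Xtr, y = train$targets, n_nodes = n_nodes,
        control = minpack.lm::nls.lm.control(maxiter = chunk)))
      p <- fit$par
      m <- mlp_unpack(p, n_nodes, n_in)
      va <- mean((validation$targets - mlp_forward(m, Xva))^2)
      if (va < va_best - 1e-12) {
        va_best <- va; p_best <- p; rises <- 0L
      } else {
        rises <- rises + 1L
        if (rises >= patience) break
      }
    }
    m <- mlp_unpack(p_best, n_nodes, n_in)
    cands[[r]] <- c(m, list(
      n_nodes = n_nodes, restart = r,
      train_mse = mean((train$targets - mlp_forward(m, Xtr))^2),
      validation_mse = va_best))
  }
  va <- vapply(cands, `[[`, 0, "validation_mse")
  nn <- vapply(cands, `[[`, 0, "n_nodes")
  ord <- order(va, nn, seq_along(cands))
  champion <- cands[[ord[1]]]
  members <- cands[ord[seq_len(min(ensemble, restarts))]]
  out <- c(champion[c("hidden_weights", "hidden_bias", "output_weights",
                      "output_bias")],
           list(n_nodes = champion$n_nodes, activation = "relu",
                input_norm = norm,
                feature_names = colnames(train$features),
                members = lapply(members, function(m)
                  m[c("hidden_weights", "hidden_bias", "output_weights",
                      "output_bias", "n_nodes")]),
                training_record = list(
                  seed = seed, restart = champion$restart,
                  n_nodes = champion$n_nodes,
                  train_mse = champion$train_mse,
                  validation_mse = champion$validation_mse,
                  candidate_validation_mse = va,
                  candidate_nodes = nn)))
  class(out) <- "ca_mlp"
  out
}

#' Predict curve magnitudes in nM
#'
#' Applies the model's stored input normalisation, aggregates the
#' ensemble members' log10 outputs (member-wise median by default, which
#' is robust to the occasional member whose rectifier surface
#' extrapolates wildly at an unseen condition corner), and
#' back-transforms.
#'
#' @param object A fitted `"ca_mlp"`.
#' @param conditions Scaled condition data frame (from
#'   [scale_conditions()]) or a prebuilt 27-column feature matrix.
#' @param type `"nM"` (default, `10^output`) or `"log10"`.
#' @param members Use the first `members` ensemble members (default all;
#'   1 = the validation-MSE champion alone).
#' @param aggregate `"median"` (default) or `"mean"` across members.
#' @param ... Unused.
#' @return Numeric vector of predicted magnitudes.
#' @export
predict.ca_mlp <- function(object, conditions, type = c("nM", "log10"),
                           members = length(object$members),
                           aggregate = c("median", "mean"), ...) {
  type <- match.arg(type)
  aggregate <- match.arg(aggregate)
  X <- if (is.matrix(conditions)) conditions else expand_features(conditions)
  Xn <- mlp_norm_apply(object$input_norm, X)
  use <- object$members[seq_len(max(1, min(members,
                                           length(object$members))))]
  preds <- sapply(use, function(m) mlp_forward(m, Xn))
  if (!is.matrix(preds)) preds <- matrix(preds, nrow = nrow(Xn))
  out <- if (aggregate == "median") apply(preds, 1, stats::median)
         else rowMeans(preds)
  if (type == "nM") 10^out else out
}

#' @export
print.ca_mlp <- function(x, ...) {
  tr <- x$training_record
  cat(sprintf(paste0("Magnitude MLP: %d rectifier node(s), 27 inputs",
                     " (%d-member ensemble)\n",
                     "  champion train MSE %.4g, validation MSE %.4g",
                     " (restart %d, seed %d)\n"),
              x$n_nodes, length(x$members), tr$train_mse,
              tr$validation_mse, tr$restart, tr$seed))
  invisible(x)
}

#' @export
coef.ca_mlp <- function(object, ...) {
  list(hidden_weights = object$hidden_weights,
       hidden_bias = object$hidden_bias,
       output_weights = object$output_weights,
       output_bias = object$output_bias)
}
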