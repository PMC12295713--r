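#' Partial least squares regression of one scalar characteristic
#'
#' Mean-centered single-response PLS (NIPALS / PLS1). Each latent component
#' has a score vector `t_i = X w_i` built from a unit loading-weight vector
#' `w_i` proportional to the X-y covariance of the deflated data; the
#' response is predicted as the linear combination of the scores,
#' `y = c_1 t_1 + c_2 t_2 + ...` plus the training mean. Variables enter on
#' their stated scales (flags in \[0,1\], doses in \[0,10\]), mean-centered
#' only, so loading weights are interpretable on those scales.
#'
#' @param X Numeric matrix of condition variables (rows = conditions).
#' @param y Numeric response vector (one scalar characteristic).
#' @param n_components Number of latent components (1 to `ncol(X)`).
#' @return Object of class `"ca_pls"`: loading weights `W` (variables x
#'   components), X-loadings `P`, response weights `C`, scores `scores`,
#'   regression coefficients `coefficients`, centering constants and the
#'   per-component explained variance of `y`.
#' @export
fit_pls <- function(X, y, n_components = 2) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2, length(y) == nrow(X))
  if (n_components < 1 || n_components > ncol(X)) {
    stop("n_components must be between 1 and ", ncol(X))
  }
  if (stats::var(y) == 0) stop("constant response; PLS undefined")
  x_mean <- colMeans(X); y_mean <- mean(y)
  E <- sweep(X, 2, x_mean); f <- y - y_mean
  ss_y <- sum(f^2)
  p <- ncol(X)
  W <- matrix(0, p, n_components); P <- matrix(0, p, n_components)
  C <- numeric(n_components); Tm <- matrix(0, nrow(X), n_components)
  expl <- numeric(n_components)
  for (k in seq_len(n_components)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break                 # residual response exhausted
    w <- w / nw
    t_k <- drop(E %*% w)
    tt <- sum(t_k^2)
    if (tt < 1e-12) break
    c_k <- sum(t_k * f) / tt
    p_k <- drop(crossprod(E, t_k)) / tt
    E <- E - tcrossprod(t_k, p_k)
    f <- f - c_k * t_k
    W[, k] <- w; P[, k] <- p_k; C[k] <- c_k; Tm[, k] <- t_k
    expl[k] <- c_k^2 * tt / ss_y
  }
  # the response may be exhausted before n_components (exactly collinear
  # fixtures); keep only the components actually extracted
  used <- which(colSums(W^2) > 0)
  if (length(used) < n_components) {
    n_components <- length(used)
    W <- W[, used, drop = FALSE]; P <- P[, used, drop = FALSE]
    C <- C[used]; Tm <- Tm[, used, drop = FALSE]; expl <- expl[used]
  }
  # y ~ X beta via beta = W (P'W)^{-1} C
  beta <- drop(W %*% solve(crossprod(P, W), C))
  vars <- colnames(X)
  if (is.null(vars)) vars <- paste0("x", seq_len(p))
  rownames(W) <- rownames(P) <- names(beta) <- vars
  out <- list(W = W, P = P, C = C, scores = Tm, coefficients = beta,
              x_mean = x_mean, y_mean = y_mean,
              explained_variance = expl, n_components = n_components,
              variables = vars)
  class(out) <- "ca_pls"
  out
}

#' Predict from a fitted PLS model
#'
#' @param object A `"ca_pls"` model.
#' @param X_new Matrix of new condition rows (same variables as training).
#' @param ... Unused.
#' @return Numeric vector of predicted characteristic values.
#' @export
predict.ca_pls <- function(object, X_new, ...) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(object$x_mean)) {
    stop("variable arity mismatch: expected ", length(object$x_mean))
  }
  drop(sweep(X_new, 2, object$x_mean) %*% object$coefficients) +
    object$y_mean
}

#' Loading weights of a fitted PLS model
#'
#' Per-variable loading weights `a_ji` for the requested components — the
#' quantities interpreted when asking which experimental variables drive a
#' curve characteristic. `type = "loadings"` returns the X-loadings `p_ji`
#' instead.
#'
#' @param model A `"ca_pls"`.
#' @param components Component indices (default first two).
#' @param type `"weights"` (default) or `"loadings"`.
#' @return Matrix (variables x components).
#' @export
pls_loadings <- function(model, components = 1:2,
                         type = c("weights", "loadings")) {
  type <- match.arg(type)
  if (max(components) > model$n_components) {
    stop("model was fitted with only ", model$n_components, " components")
  }
  M <- if (type == "weights") model$W else model$P
  M[, components, drop = FALSE]
}

#' @export
print.ca_pls <- function(x, ...) {
  cat(sprintf("PLS1 regression: %d component(s), %d variables\n",
              x$n_components, length(x$variables)))
  cat("  explained variance of response:",
      paste(sprintf("%.3f", x$explained_variance), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.ca_pls <- function(object, ...) object$coefficients

#' Fit the four characteristic-wise PLS models
#'
#' One PLS1 model per scalar characteristic (magnitude, tmax, ylast,
#' absdev) on the scaled condition variables.
#'
#' @param X Condition matrix (6 variables, or 7 with the drug flag).
#' @param features Scalar feature table from [scalar_feature_table()],
#'   aligned with the rows of `X`.
#' @param n_components Components per model (default 2).
#' @param log_magnitude Model log10(magnitude) instead of raw nM (default
#'   `TRUE`, consistent with the magnitude network's target).
#' @return Named list of `"ca_pls"` models.
#' @export
fit_pls_characteristics <- function(X, features, n_components = 2,
                                    log_magnitude = TRUE) {
  y_list <- list(
    magnitude = if (log_magnitude) log10(features$magnitude_nM)
                else features$magnitude_nM,
    tmax = features$tmax, ylast = features$ylast, absdev = features$absdev)
  lapply(y_list, function(y) fit_pls(X, y, n_components))
}

#' PLS with the calcium-entry-blocking drug as an extra variable
#'
#' Fits the 7-variable (six conditions + drug flag) PLS models on a design
#' containing both drug and no-drug rows, and reports how close the drug's
#' loading sits to each inhibitor's loading in the component-1/2 plane. A
#' drug acting as a calcium-entry blocker is expected to land near EGTA.
#'
#' @param X Condition matrix including a `drug` column with both 0 and 1
#'   entries.
#' @param features Scalar feature table aligned with `X`.
#' @param n_components Components per model (default 2).
#' @return List with `models` (per characteristic) and `report`: a data
#'   frame of Euclidean distances in the component-1/2 loading plane from
#'   `drug` to every other variable, per characteristic.
#' @export
drug_augmented_pls <- function(X, features, n_components = 2) {
  X <- as.matrix(X)
  if (!"drug" %in% colnames(X)) stop("X must contain a drug column")
  if (length(unique(X[, "drug"])) < 2) {
    stop("drug column is constant; need both drug and no-drug rows")
  }
  models <- fit_pls_characteristics(X, features, n_components)
  rows <- list()
  for (ch in names(models)) {
    L <- pls_loadings(models[[ch]], 1:2)
    others <- setdiff(rownames(L), "drug")
    d <- vapply(others, function(v)
      sqrt(sum((L["drug", ] - L[v, ])^2)), 0)
    rows[[ch]] <- data.frame(characteristic = ch, variable = others,
                             distance_to_drug = unname(d))
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(models = models, report = report)
}
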