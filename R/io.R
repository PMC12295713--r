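#' Read raw calcium curves from a long-format CSV
#'
#' Expects columns `exp_id`, `time_s`, `ca_nM`; rows are grouped by
#' experiment and sorted by time, and the sampling interval is inferred and
#' checked for uniformity.
#'
#' @param path CSV file path.
#' @return Named list of `"raw_curve"` objects.
#' @export
read_curves <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("exp_id", "time_s", "ca_nM")
  if (!all(need %in% names(df))) {
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  bad <- which(df$ca_nM < 0)
  if (length(bad)) {
    stop("negative [Ca2+]i at row ", bad[1], " (exp ", df$exp_id[bad[1]], ")")
  }
  split_rows <- split(df, df$exp_id)
  curves <- lapply(split_rows, function(g) {
    g <- g[order(g$time_s), ]
    if (anyDuplicated(g$time_s)) {
      stop("duplicated timestamps for exp ", g$exp_id[1])
    }
    dt <- unique(round(diff(g$time_s), 9))
    structure(list(exp_id = g$exp_id[1], times = g$time_s,
                   values = g$ca_nM,
                   sampling_interval = if (length(dt) == 1) dt else NA_real_),
              class = "raw_curve")
  })
  curves[order(as.numeric(names(curves)))]
}

#' Write raw curves to a long-format CSV
#'
#' @param curves List of `"raw_curve"` objects.
#' @param path Output CSV path.
#' @param provenance Optional character vector written as `#`-prefixed
#'   header lines (settings, seeds).
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path, provenance = NULL) {
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(exp_id = cv$exp_id, time_s = cv$times, ca_nM = cv$values)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste("#", provenance), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write the design matrix (with split labels) to CSV
#'
#' @param conditions Condition data frame.
#' @param splits Optional `"split_assignment"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(conditions, path, splits = NULL) {
  df <- conditions
  if (!is.null(splits)) {
    df$split <- ifelse(df$exp_id %in% splits$test_ids, "test",
                ifelse(df$exp_id %in% splits$validation_ids, "validation",
                       "train"))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Desk-scale budgets: the trend-network search covers 30 architectures
#' with 5 restarts each and the magnitude network 100 restarts, against the
#' default 72-condition synthetic design.
#'
#' @param seed Master seed for generation, training and search.
#' @param out_dir Output directory (`NULL` = no files written).
#' @return A configuration list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL) {
  list(seed = seed, out_dir = out_dir,
       generator = generator_params(),
       sg_window = 11, sg_polyorder = 3,
       validation_ids = default_validation_ids(),
       test_ids = default_test_ids(),
       mlp = list(node_range = 1:10, restarts = 200, ensemble = 20),
       narx = list(budget = 30, restarts = 5, final_restarts = 8,
                   ensemble = 8,
                   search_maxit = list(sp = 60, seg = 60, cl = 0),
                   final_maxit = list(sp = 100, seg = 200, cl = 600),
                   stride = 2L, seg_len = 61L),
       pls = list(n_components = 2))
}

#' Run the full modelling pipeline
#'
#' Generates (or loads) the raw curves, preprocesses them, trains the
#' magnitude and trend networks on the training split, evaluates both on
#' the held-out splits, runs the one-at-a-time sensitivity sweep, and fits
#' the four characteristic-wise PLS models (58 training conditions, the
#' remaining 14 as PLS test set). When `out_dir` is set, every intermediate
#' is written with a provenance header and listed in a manifest.
#'
#' @param config Configuration from [pipeline_config()].
#' @param curves Optional pre-loaded list of `"raw_curve"`s; by default the
#'   synthetic generator supplies them.
#' @return List with the design, splits, fitted models, per-split trend and
#'   magnitude R-squared values, the OAT table, PLS models and (if written)
#'   the output manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), curves = NULL) {
  if (is.null(curves) && is.null(config$generator)) {
    stop("config provides neither curves nor a generator")
  }
  conditions <- build_design_matrix()
  if (is.null(curves)) {
    curves <- generate_dataset(conditions, config$generator, config$seed)
  }
  splits <- assign_splits(conditions, config$validation_ids, config$test_ids)
  prep <- preprocess_curves(curves, config$sg_window, config$sg_polyorder)
  scaled_cond <- scale_conditions(conditions)
  X27 <- expand_features(scaled_cond)
  feats <- scalar_feature_table(prep$uniform)

  pick <- function(ids) {
    keep <- match(as.character(ids), names(prep$scaled))
    list(features = X27[as.character(ids), , drop = FALSE],
         targets = do.call(rbind, lapply(prep$scaled[keep], `[[`, "values")),
         log_mag = log10(feats$magnitude_nM[match(ids, feats$exp_id)]))
  }
  tr <- pick(splits$train_ids)
  va <- pick(splits$validation_ids)
  te <- pick(splits$test_ids)

  mlp <- fit_mlp(list(features = tr$features, targets = tr$log_mag),
                 list(features = va$features, targets = va$log_mag),
                 node_range = config$mlp$node_range,
                 restarts = config$mlp$restarts, seed = config$seed,
                 ensemble = config$mlp$ensemble)
  search <- search_narx(list(features = tr$features, targets = tr$targets),
                        list(features = va$features, targets = va$targets),
                        budget = config$narx$budget,
                        restarts = config$narx$restarts,
                        seed = config$seed,
                        search_maxit = config$narx$search_maxit,
                        final_maxit = config$narx$final_maxit,
                        final_restarts = config$narx$final_restarts,
                        ensemble = config$narx$ensemble,
                        stride = config$narx$stride,
                        seg_len = config$narx$seg_len)
  narx <- search$model

  r2 <- list(
    trend_train = trend_r2(narx, tr$features, tr$targets),
    trend_validation = trend_r2(narx, va$features, va$targets),
    trend_test = trend_r2(narx, te$features, te$targets),
    magnitude_log_train = r2_score(tr$log_mag,
                                   predict(mlp, tr$features, "log10")),
    magnitude_log_test = r2_score(c(va$log_mag, te$log_mag),
                                  predict(mlp, rbind(va$features,
                                                     te$features), "log10")))

  oat <- oat_sweep(mlp, narx)

  Xpls <- as.matrix(scaled_cond[, c("col", "crp", "thr", "egta", "ai",
                                    "thap")])
  rownames(Xpls) <- scaled_cond$exp_id
  in_train <- conditions$exp_id %in% splits$train_ids
  pls <- fit_pls_characteristics(Xpls[in_train, ], feats[in_train, ],
                                 config$pls$n_components)
  pls_test_r2 <- vapply(names(pls), function(ch) {
    y <- switch(ch, magnitude = log10(feats$magnitude_nM),
                feats[[ch]])[!in_train]
    r2_score(y, predict(pls[[ch]], Xpls[!in_train, ]))
  }, 0)

  out <- list(conditions = conditions, splits = splits, curves = curves,
              preprocessed = prep, features = feats, mlp = mlp, narx = narx,
              narx_search = search[c("architecture", "validation_r2",
                                     "search_table")],
              r2 = r2, oat = oat, pls = pls, pls_test_r2 = pls_test_r2,
              seed = config$seed)
  if (!is.null(config$out_dir)) {
    out$manifest <- write_pipeline_outputs(out, config)
  }
  out
}

write_pipeline_outputs <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- paste0("seed=", config$seed, " sg_window=", config$sg_window,
                 " sg_polyorder=", config$sg_polyorder)
  paths <- character()
  p <- file.path(config$out_dir, "curves.csv")
  write_curves(res$curves, p, provenance = prov)
  paths["curves"] <- p
  p <- file.path(config$out_dir, "design.csv")
  write_design(res$conditions, p, res$splits)
  paths["design"] <- p
  p <- file.path(config$out_dir, "scalar_features.csv")
  utils::write.csv(res$features, p, row.names = FALSE)
  paths["scalar_features"] <- p
  p <- file.path(config$out_dir, "oat.csv")
  utils::write.csv(as.data.frame(res$oat), p, row.names = FALSE)
  paths["oat"] <- p
  for (ch in names(res$pls)) {
    p <- file.path(config$out_dir, paste0("pls_loadings_", ch, ".csv"))
    L <- pls_loadings(res$pls[[ch]], 1:2)
    utils::write.csv(data.frame(variable = rownames(L),
                                component1 = L[, 1], component2 = L[, 2]),
                     p, row.names = FALSE)
    paths[paste0("pls_", ch)] <- p
  }
  p <- file.path(config$out_dir, "models.json")
  jsonlite::write_json(
    list(seed = config$seed,
         mlp = lapply(coef(res$mlp), unclass),
         mlp_record = res$mlp$training_record[c("seed", "restart",
                                                "n_nodes", "train_mse",
                                                "validation_mse")],
         narx = list(arch = res$narx$arch, delays = res$narx$delays,
                     n_members = if (inherits(res$narx, "ca_narx_ensemble"))
                       length(res$narx$members) else 1L),
         narx_weights = lapply(
           narx_best_member(res$narx)[c("W", "H1", "L2", "H2", "L3", "H3",
                                        "L4", "b1", "b2", "b3", "b4")],
           unclass)),
    p, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  paths["models"] <- p
  manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(list(seed = config$seed, provenance = prov,
                            outputs = as.list(paths)),
                       manifest, auto_unbox = TRUE)
  paths["manifest"] <- manifest
  paths
}
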