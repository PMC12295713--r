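#' Agonist dose levels and inhibitor crossing of the default condition matrix
#'
#' The default design crosses three platelet agonists with extracellular
#' calcium removal (EGTA vs. added CaCl2), autocrine-mediator inhibition
#' (apyrase + indomethacin, "AI") and SERCA inhibition (thapsigargin).
#' Dose units are ug/mL for collagen and CRP and nM for thrombin.
#'
#' @return A list with per-agonist dose levels, per-agonist maximal doses and
#'   the inhibitor flag combinations crossed with each block.
#' @export
default_design_spec <- function() {
  list(
    doses = list(
      collagen = c(1, 3, 10, 30),   # ug/mL
      crp      = c(1, 10),          # ug/mL
      thrombin = c(0.3, 1, 3, 10)   # nM
    ),
    max_doses = c(collagen = 30, crp = 10, thrombin = 10),
    # flag rows are (egta, ai, thap); controls get the full 2^3 crossing,
    # collagen/thrombin a 6-combination subset (thapsigargin crossed with
    # EGTA only), CRP the full crossing
    control_flags  = expand_flags(full = TRUE),
    agonist_flags  = list(
      collagen = expand_flags(full = FALSE),
      crp      = expand_flags(full = TRUE),
      thrombin = expand_flags(full = FALSE)
    )
  )
}

# flag combinations in a fixed documented order; the reduced set crosses
# thapsigargin with EGTA only (ai = 0)
expand_flags <- function(full = TRUE) {
  if (full) {
    f <- rbind(
      c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 0, 0),
      c(0, 0, 1), c(0, 1, 1), c(1, 1, 1), c(1, 0, 1)
    )
  } else {
    f <- rbind(
      c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 0, 0),
      c(0, 0, 1), c(1, 0, 1)
    )
  }
  colnames(f) <- c("egta", "ai", "thap")
  f
}

#' Build the experimental condition matrix
#'
#' Enumerates the 72-condition single-donor design (vehicle/thapsigargin
#' controls in experiments 1-8 covering all eight inhibitor-flag
#' combinations, collagen in 9-32, CRP in 33-48, thrombin in 49-72), or the
#' separate 16-condition drug-validation design in which maximal agonist (or
#' thapsigargin-only) stimulation is crossed with EGTA/CaCl2 and the
#' calcium-entry-blocking drug 2APB.
#'
#' @param spec Design specification as returned by [default_design_spec()].
#' @param include_drug_block If `TRUE`, return the 16-condition 2APB design
#'   instead of the main 72-condition design.
#' @return A data frame of conditions with columns `exp_id`, `agonist`,
#'   `dose`, `dose_units`, `egta`, `ai`, `thap`, `drug`.
#' @export
build_design_matrix <- function(spec = default_design_spec(),
                                include_drug_block = FALSE) {
  if (is.null(spec$doses) || length(spec$doses) == 0L) {
    return(empty_design())
  }
  for (ag in names(spec$doses)) {
    d <- spec$doses[[ag]]
    if (any(d <= 0) || any(d > spec$max_doses[[ag]])) {
      stop("dose level outside spec for agonist ", ag)
    }
  }
  if (include_drug_block) {
    return(drug_design(spec))
  }
  rows <- list()
  cf <- spec$control_flags
  for (i in seq_len(nrow(cf))) {
    rows[[length(rows) + 1L]] <- cond_row("none", 0, cf[i, ])
  }
  for (ag in c("collagen", "crp", "thrombin")) {
    fl <- spec$agonist_flags[[ag]]
    for (dose in spec$doses[[ag]]) {
      for (i in seq_len(nrow(fl))) {
        rows[[length(rows) + 1L]] <- cond_row(ag, dose, fl[i, ])
      }
    }
  }
  des <- do.call(rbind, rows)
  des$exp_id <- seq_len(nrow(des))
  des <- des[, c("exp_id", "agonist", "dose", "dose_units",
                 "egta", "ai", "thap", "drug")]
  if (anyDuplicated(des$exp_id)) stop("duplicate exp_id in design")
  validate_conditions(des)
  des
}

drug_design <- function(spec) {
  rows <- list()
  blocks <- list(
    list(agonist = "collagen", dose = max(spec$doses$collagen), thap = 0),
    list(agonist = "crp",      dose = max(spec$doses$crp),      thap = 0),
    list(agonist = "thrombin", dose = max(spec$doses$thrombin), thap = 0),
    list(agonist = "none",     dose = 0,                        thap = 1)
  )
  for (b in blocks) for (egta in 0:1) for (drug in 0:1) {
    rows[[length(rows) + 1L]] <- cond_row(
      b$agonist, b$dose, c(egta = egta, ai = 0, thap = b$thap), drug = drug)
  }
  des <- do.call(rbind, rows)
  des$exp_id <- seq_len(nrow(des))
  des <- des[, c("exp_id", "agonist", "dose", "dose_units",
                 "egta", "ai", "thap", "drug")]
  validate_conditions(des)
  des
}

cond_row <- function(agonist, dose, flags, drug = 0) {
  units <- switch(agonist, thrombin = "nM", none = "", "ug/mL")
  data.frame(exp_id = NA_integer_, agonist = agonist, dose = dose,
             dose_units = units, egta = unname(flags[["egta"]]),
             ai = unname(flags[["ai"]]), thap = unname(flags[["thap"]]),
             drug = drug, stringsAsFactors = FALSE)
}

empty_design <- function() {
  data.frame(exp_id = integer(), agonist = character(), dose = numeric(),
             dose_units = character(), egta = integer(), ai = integer(),
             thap = integer(), drug = integer(), stringsAsFactors = FALSE)
}

validate_conditions <- function(des) {
  stopifnot(all(des$dose >= 0),
            all((des$dose == 0) == (des$agonist == "none")),
            all(des$egta %in% 0:1), all(des$ai %in% 0:1),
            all(des$thap %in% 0:1), all(des$drug %in% 0:1))
  invisible(des)
}

#' Scale conditions onto the network input ranges
#'
#' Inhibitor flags stay in \[0, 1\]; agonist doses are mapped linearly onto
#' \[0, 10\] so that the maximal dose of each agonist reaches exactly 10.
#' A value of 0 means the agonist or inhibitor is absent.
#'
#' @param conditions Condition data frame from [build_design_matrix()].
#' @param max_doses Named vector of per-agonist maximal doses.
#' @param include_drug Keep the drug flag as a seventh column (used only by
#'   the PLS analysis, never by the networks).
#' @return Data frame with columns `exp_id`, `col`, `crp`, `thr`, `egta`,
#'   `ai`, `thap` (and `drug` if requested).
#' @export
scale_conditions <- function(conditions,
                             max_doses = default_design_spec()$max_doses,
                             include_drug = FALSE) {
  validate_conditions(conditions)
  stopifnot(all(max_doses > 0))
  ag <- conditions$agonist
  dose <- conditions$dose
  chan <- function(name) {
    v <- ifelse(ag == name, 10 * dose / max_doses[[name]], 0)
    if (any(v > 10 + 1e-12)) stop("dose exceeds stated maximum for ", name)
    v
  }
  out <- data.frame(
    exp_id = conditions$exp_id,
    col = chan("collagen"), crp = chan("crp"), thr = chan("thrombin"),
    egta = conditions$egta, ai = conditions$ai, thap = conditions$thap)
  if (include_drug) out$drug <- conditions$drug
  out
}

#' Assign train / validation / test splits
#'
#' Curves named in `validation_ids` and `test_ids` are held out; every other
#' experiment forms the training set. The default hold-outs reproduce a
#' 58 / 7 / 7 partition of the 72-condition design, with a thrombin-heavy
#' test set (experiments 63, 67, 70 and 72 among them).
#'
#' @param conditions Condition data frame.
#' @param validation_ids,test_ids Integer vectors of `exp_id`s.
#' @return Object of class `"split_assignment"`: list with `train_ids`,
#'   `validation_ids`, `test_ids`.
#' @export
assign_splits <- function(conditions,
                          validation_ids = default_validation_ids(),
                          test_ids = default_test_ids()) {
  ids <- conditions$exp_id
  unknown <- setdiff(c(validation_ids, test_ids), ids)
  if (length(unknown)) stop("unknown exp_id: ", paste(unknown, collapse = ", "))
  if (length(intersect(validation_ids, test_ids))) {
    stop("validation and test sets overlap")
  }
  out <- list(train_ids = setdiff(ids, c(validation_ids, test_ids)),
              validation_ids = validation_ids, test_ids = test_ids)
  class(out) <- "split_assignment"
  out
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("Split assignment:", length(x$train_ids), "train /",
      length(x$validation_ids), "validation /",
      length(x$test_ids), "test\n")
  invisible(x)
}

#' @rdname assign_splits
#' @export
default_validation_ids <- function() c(15L, 22L, 30L, 36L, 42L, 49L, 58L)

#' @rdname assign_splits
#' @export
default_test_ids <- function() c(24L, 27L, 44L, 63L, 67L, 70L, 72L)
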