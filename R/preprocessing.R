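#' Filter features by missingness
#'
#' A feature is retained iff its missing fraction is at most `threshold`
#' (strictly more is excluded), matching the ">20% missing excluded" rule.
#'
#' @param data Data frame or matrix of feature columns (or a cohort tibble
#'   with `features` restricting the columns considered).
#' @param threshold Maximum tolerated missing fraction, in (0, 1).
#' @param features Optional character vector of columns to consider.
#' @return Character vector of retained feature names.
#' @export
filter_missingness <- function(data, threshold = 0.20, features = NULL) {
  assert_that(threshold > 0 && threshold < 1, "`threshold` must be in (0, 1)")
  if (!is.null(features)) data <- data[features]
  m <- as.matrix(data)
  frac <- colMeans(is.na(m))
  names(frac)[frac <= threshold]
}

#' Fit a leakage-safe imputation + scaling transform
#'
#' Medians, means and SDs are computed on the training rows only; the
#' transform imputes missing values with the training median and then
#' z-standardizes with the training mean/SD. Features entirely missing in
#' training, or with zero SD after imputation, are dropped with a warning.
#'
#' @param data Data frame with the feature columns.
#' @param train_idx Integer or logical index of training rows.
#' @param features Feature columns to transform.
#' @return A `fitted_transform` with the retained features and their
#'   training statistics.
#' @export
fit_transform <- function(data, train_idx, features) {
  m <- as.matrix(data[features])
  storage.mode(m) <- "double"
  tr <- m[train_idx, , drop = FALSE]
  assert_that(nrow(tr) > 0, "empty training index")
  med <- apply(tr, 2, median, na.rm = TRUE)
  all_na <- is.na(med)
  if (any(all_na)) {
    rlang::warn(paste0("dropping feature(s) entirely missing in training: ",
                       paste(features[all_na], collapse = ", ")))
  }
  imp <- tr
  for (j in seq_len(ncol(imp))) imp[is.na(imp[, j]), j] <- med[j]
  mu <- colMeans(imp)
  sdv <- apply(imp, 2, sd)
  zero_sd <- !all_na & (is.na(sdv) | sdv == 0)
  if (any(zero_sd)) {
    rlang::warn(paste0("dropping constant training feature(s): ",
                       paste(features[zero_sd], collapse = ", ")))
  }
  keep <- !all_na & !zero_sd
  structure(list(features = features[keep], median = med[keep],
                 mean = mu[keep], sd = sdv[keep]),
            class = "fitted_transform")
}

#' @rdname fit_transform
#' @param transform A `fitted_transform`.
#' @return `apply_transform()` returns the imputed, standardized numeric
#'   matrix over the retained features.
#' @export
apply_transform <- function(transform, data) {
  assert_that(inherits(transform, "fitted_transform"),
              "`transform` must come from fit_transform()")
  m <- as.matrix(data[transform$features])
  storage.mode(m) <- "double"
  for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- transform$median[j]
  scale(m, center = transform$mean, scale = transform$sd)[, , drop = FALSE]
}

#' Build a stratified nested cross-validation fold plan
#'
#' Outer folds partition the discovery-region participants of one
#' case/control contrast, stratified by case status (per-fold case counts
#' differ by at most one). All hold-out-region participants of the contrast
#' form the geographic hold-out set, disjoint from every fold. Participant
#' ids are sorted before the seeded shuffle so the plan is reproducible.
#'
#' @param cohort Cohort tibble with a `region` column.
#' @param frame A `phenotype_frame`.
#' @param phenotype Phenotype code to contrast against the shared controls.
#' @param n_folds Number of outer folds (default 5).
#' @param seed Integer seed.
#' @param discovery Region label of the discovery set.
#' @return A `fold_plan`: list with `assign` (tibble `participant_id`,
#'   `role`, `fold`), `holdout` (tibble `participant_id`, `role`),
#'   `n_folds`, `seed`.
#' @export
make_fold_plan <- function(cohort, frame, phenotype, n_folds = 5, seed,
                           discovery = "discovery") {
  cases <- frame_cases(frame, phenotype)
  controls <- frame_controls(frame)
  reg <- setNames(cohort$region, cohort$participant_id)
  cases <- cases[!is.na(reg[cases])]
  controls <- controls[!is.na(reg[controls])]
  disc_cases <- sort(cases[reg[cases] == discovery])
  disc_ctrl <- sort(controls[reg[controls] == discovery])
  hold <- tibble::tibble(
    participant_id = c(cases[reg[cases] != discovery],
                       controls[reg[controls] != discovery]),
    role = rep(c("case", "control"),
               c(sum(reg[cases] != discovery), sum(reg[controls] != discovery))))
  assert_that(length(disc_cases) + length(disc_ctrl) > 0,
              "discovery region is empty for this contrast")
  if (length(disc_cases) < 2 * n_folds) {
    rlang::abort(sprintf(
      "only %d discovery cases for %d-fold stratification; use fewer folds",
      length(disc_cases), n_folds))
  }
  assign_strat <- function(ids, what) {
    ids <- sample(ids)  # seeded below
    tibble::tibble(participant_id = ids, role = what,
                   fold = rep_len(seq_len(n_folds), length(ids)))
  }
  assign <- with_seed(seed, dplyr::bind_rows(assign_strat(disc_cases, "case"),
                                             assign_strat(disc_ctrl, "control")))
  structure(list(assign = assign, holdout = hold, n_folds = n_folds,
                 seed = as.integer(seed), phenotype = phenotype),
            class = "fold_plan")
}

#' Serialize a fold plan to JSON text (for audit)
#' @param plan A `fold_plan`.
#' @param path Optional path to write to.
#' @return The JSON string, invisibly if written to `path`.
#' @export
fold_plan_json <- function(plan, path = NULL) {
  js <- jsonlite::toJSON(list(phenotype = plan$phenotype, seed = plan$seed,
                              n_folds = plan$n_folds, assign = plan$assign,
                              holdout = plan$holdout),
                         dataframe = "columns", auto_unbox = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
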