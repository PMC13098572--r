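#' Model specification for the discrimination harness
#'
#' @param algorithm One of `"logistic"` (ridge-regularized logistic
#'   regression), `"random_forest"`, `"xgboost"`.
#' @param feature_set One of `"metabolites"`, `"clinical"`, `"combined"`.
#' @param grid Hyperparameter grid: a list of named parameter lists. `NULL`
#'   uses the defaults — logistic: lambda in \{0.01, 0.1, 1, 10\}; xgboost:
#'   200 trees, depth \{3, 6\}, learning rate \{0.05, 0.1\}; random forest:
#'   300 trees, depth \{unlimited, 8\}.
#' @param seed Integer seed for every stochastic step of the harness.
#' @return A `model_spec`.
#' @export
model_spec <- function(algorithm = c("logistic", "random_forest", "xgboost"),
                       feature_set = c("metabolites", "clinical", "combined"),
                       grid = NULL, seed) {
  algorithm <- match.arg(algorithm)
  feature_set <- match.arg(feature_set)
  if (missing(seed)) rlang::abort("model_spec(): `seed` must be given explicitly")
  if (is.null(grid)) grid <- default_grid(algorithm)
  assert_that(length(grid) >= 1, "hyperparameter grid must be non-empty")
  structure(list(algorithm = algorithm, feature_set = feature_set,
                 grid = grid, seed = as.integer(seed),
                 id = paste(algorithm, feature_set, sep = "/")),
            class = "model_spec")
}

default_grid <- function(algorithm) {
  switch(algorithm,
    logistic = purrr::map(c(0.01, 0.1, 1, 10), ~list(lambda = .x)),
    xgboost = purrr::pmap(expand.grid(nrounds = 200, max_depth = c(3, 6),
                                      eta = c(0.05, 0.1)), list),
    random_forest = purrr::pmap(expand.grid(num_trees = 300,
                                            max_depth = c(0, 8)), list))
}

#' ROC area under the curve
#'
#' The probability that a random case outscores a random control, with ties
#' counted one-half (the normalized Mann-Whitney U statistic).
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels 0/1 or logical labels (1 = case).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) rlang::abort("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified bootstrap percentile CI for the AUC
#'
#' Resamples participants with replacement within each class (so both
#' classes persist in every resample) and returns the percentile 2.5/97.5
#' interval of the AUC over `B` resamples.
#'
#' @param scores,labels As in [roc_auc()].
#' @param B Number of bootstrap iterations (default 1000).
#' @param seed Integer seed.
#' @return Named numeric `c(lower, upper)`.
#' @export
bootstrap_auc_ci <- function(scores, labels, B = 1000, seed) {
  labels <- as.integer(as.logical(labels))
  i1 <- which(labels == 1); i0 <- which(labels == 0)
  assert_that(length(i1) > 0 && length(i0) > 0, "both classes must be present")
  aucs <- with_seed(seed, vapply(seq_len(B), function(b) {
    j <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
    roc_auc(scores[j], labels[j])
  }, numeric(1)))
  q <- unname(quantile(aucs, c(0.025, 0.975)))
  c(lower = q[1], upper = q[2])
}

#' Events-per-variable overfitting flag
#'
#' @param n_cases,n_features Case and feature counts.
#' @param threshold Flag when `EPV = n_cases / n_features` is strictly below
#'   this (default 5; 0 never flags).
#' @return List with `epv` and `flagged`.
#' @export
epv_flag <- function(n_cases, n_features, threshold = 5) {
  epv <- n_cases / n_features
  assert_that(epv > 0, "EPV must be positive")
  list(epv = epv, flagged = epv < threshold)
}

resolve_features <- function(cohort, feature_set, missing_threshold = 0.20) {
  met <- filter_missingness(cohort, missing_threshold,
                            metabolite_features(cohort))
  cli <- filter_missingness(cohort, missing_threshold,
                            clinical_features(cohort))
  switch(feature_set, metabolites = met, clinical = cli,
         combined = c(met, cli))
}

inv_prevalence_weights <- function(y) {
  n <- length(y)
  w1 <- n / (2 * sum(y == 1)); w0 <- n / (2 * sum(y == 0))
  ifelse(y == 1, w1, w0)
}

pad1 <- function(x) {
  if (ncol(x) >= 2) return(x)
  cbind(x, `..pad..` = 0)
}

fit_model <- function(algorithm, x, y, weights, params, seed) {
  fit <- switch(algorithm,
    logistic = glmnet::glmnet(pad1(x), y, family = "binomial", alpha = 0,
                              lambda = params$lambda, weights = weights),
    random_forest = ranger::ranger(
      y = factor(y, levels = c(0, 1)), x = as.data.frame(x),
      probability = TRUE, num.trees = params$num_trees,
      max.depth = params$max_depth, case.weights = weights,
      seed = seed, num.threads = 1),
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y, weight = weights),
      nrounds = params$nrounds, verbose = 0))
  structure(list(algorithm = algorithm, fit = fit, params = params,
                 features = colnames(x)),
            class = "atlas_model")
}

predict_model <- function(model, x) {
  x <- x[, model$features[model$features != "..pad.."], drop = FALSE]
  switch(model$algorithm,
    logistic = {
      m <- as.numeric(predict(model$fit, pad1(x), type = "link",
                              s = model$params$lambda))
      list(margin = m, prob = stats::plogis(m))
    },
    random_forest = {
      p <- predict(model$fit, data = as.data.frame(x),
                   num.threads = 1)$predictions[, "1"]
      list(margin = p, prob = p)
    },
    xgboost = {
      d <- xgboost::xgb.DMatrix(x)
      m <- predict(model$fit, d, outputmargin = TRUE)
      list(margin = m, prob = stats::plogis(m))
    })
}

threshold_metrics <- function(prob, labels, threshold = 0.5) {
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(sensitivity = sens, specificity = spec,
       balanced_accuracy = mean(c(sens, spec)))
}

# stratified inner-fold assignment for ids already restricted to training
inner_fold_assign <- function(ids, roles, n_folds, seed) {
  with_seed(seed, {
    out <- integer(length(ids))
    for (r in unique(roles)) {
      i <- which(roles == r)
      out[i[order(ids[i])][sample(length(i))]] <- rep_len(seq_len(n_folds),
                                                          length(i))
    }
    out
  })
}

#' Nested cross-validated discrimination of one phenotype
#'
#' Inner folds select the hyperparameter configuration maximizing mean inner
#' AUC; outer folds are scored by models refit on the outer-training set with
#' the selected configuration. All preprocessing (median imputation,
#' z-scoring) is fit strictly within training folds. The headline estimate is
#' the pooled AUC over concatenated outer-fold scores, with a stratified
#' bootstrap CI; per-fold AUCs, threshold metrics at probability 0.5,
#' geographic hold-out performance and an events-per-variable flag are also
#' reported.
#'
#' @param cohort Cohort tibble.
#' @param frame A `phenotype_frame`.
#' @param spec A [model_spec()].
#' @param plan A [make_fold_plan()] for the same phenotype.
#' @param features Optional explicit feature set (overrides the spec's
#'   feature-set resolution) — used for parsimonious-subset evaluation.
#' @param inner_folds Number of inner folds (default 5).
#' @param bootstrap_B Bootstrap iterations for CIs (default 1000).
#' @param epv_threshold EPV flag threshold (default 5).
#' @param keep_model Keep the final discovery-fitted pipeline (needed for
#'   attribution analysis).
#' @return A `discrimination_result`.
#' @export
run_nested_cv <- function(cohort, frame, spec, plan, features = NULL,
                          inner_folds = 5, bootstrap_B = 1000,
                          epv_threshold = 5, keep_model = FALSE) {
  assert_that(inherits(spec, "model_spec"), "`spec` must come from model_spec()")
  if (is.null(features)) features <- resolve_features(cohort, spec$feature_set)
  assert_that(length(features) >= 1, "no features resolved")
  rows <- match(plan$assign$participant_id, cohort$participant_id)
  assert_that(!anyNA(rows), "fold plan references unknown participants")
  dat <- cohort[rows, , drop = FALSE]
  y <- as.integer(plan$assign$role == "case")
  folds <- plan$assign$fold
  per_fold_cases <- tapply(y, folds, sum)
  if (any(per_fold_cases < 2)) {
    rlang::abort("degenerate folds: fewer than 2 cases in an outer fold")
  }

  score_config <- function(tr_idx, va_idx, params, seed) {
    ft <- suppressWarnings(fit_transform(dat, tr_idx, features))
    xtr <- apply_transform(ft, dat[tr_idx, , drop = FALSE])
    xva <- apply_transform(ft, dat[va_idx, , drop = FALSE])
    mod <- fit_model(spec$algorithm, xtr, y[tr_idx],
                     inv_prevalence_weights(y[tr_idx]), params, seed)
    predict_model(mod, xva)
  }

  outer_scores <- list()
  chosen <- character(plan$n_folds)
  grid_ids <- vapply(spec$grid, function(g)
    paste(names(g), unlist(g), sep = "=", collapse = ","), character(1))
  for (f in seq_len(plan$n_folds)) {
    tr <- which(folds != f); va <- which(folds == f)
    if (length(spec$grid) == 1) {
      best <- 1L
    } else {
      iseed <- derive_seed(spec$seed, paste0("inner", f))
      ifold <- inner_fold_assign(plan$assign$participant_id[tr],
                                 plan$assign$role[tr], inner_folds, iseed)
      mean_auc <- vapply(seq_along(spec$grid), function(g) {
        aucs <- vapply(seq_len(inner_folds), function(k) {
          itr <- tr[ifold != k]; iva <- tr[ifold == k]
          pr <- score_config(itr, iva, spec$grid[[g]],
                             derive_seed(iseed, paste(g, k)))
          roc_auc(pr$margin, y[iva])
        }, numeric(1))
        mean(aucs)
      }, numeric(1))
      best <- which.max(mean_auc)  # ties -> first config in grid order
    }
    chosen[f] <- grid_ids[best]
    pr <- score_config(tr, va, spec$grid[[best]],
                       derive_seed(spec$seed, paste0("outer", f)))
    outer_scores[[f]] <- tibble::tibble(
      participant_id = plan$assign$participant_id[va], fold = f,
      label = y[va], margin = pr$margin, prob = pr$prob)
  }
  scores <- dplyr::bind_rows(outer_scores)
  pooled_auc <- roc_auc(scores$margin, scores$label)
  fold_auc <- vapply(split(scores, scores$fold),
                     function(d) roc_auc(d$margin, d$label), numeric(1))
  ci <- bootstrap_auc_ci(scores$margin, scores$label, B = bootstrap_B,
                         seed = derive_seed(spec$seed, "bootstrap"))
  aux <- threshold_metrics(scores$prob, scores$label)

  # final pipeline on full discovery, modal selected configuration
  modal <- names(sort(table(factor(chosen, levels = grid_ids)),
                      decreasing = TRUE))[1]
  best_cfg <- spec$grid[[match(modal, grid_ids)]]
  ft_full <- suppressWarnings(fit_transform(dat, seq_len(nrow(dat)), features))
  x_full <- apply_transform(ft_full, dat)
  final <- fit_model(spec$algorithm, x_full, y, inv_prevalence_weights(y),
                     best_cfg, derive_seed(spec$seed, "final"))
  pipeline <- structure(list(transform = ft_full, model = final,
                             spec = spec), class = "fitted_pipeline")

  hold <- evaluate_holdout(pipeline, cohort, plan$holdout,
                           bootstrap_B = bootstrap_B,
                           seed = derive_seed(spec$seed, "holdout"))
  ev <- epv_flag(sum(y == 1), length(ft_full$features), epv_threshold)

  structure(list(
    phenotype = plan$phenotype, spec_id = spec$id,
    algorithm = spec$algorithm, feature_set = spec$feature_set,
    features = ft_full$features, chosen_config = chosen,
    fold_auc = fold_auc, pooled_auc = pooled_auc,
    ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
    sensitivity = aux$sensitivity, specificity = aux$specificity,
    balanced_accuracy = aux$balanced_accuracy,
    holdout_auc = hold$auc, holdout_ci_lower = hold$ci[["lower"]],
    holdout_ci_upper = hold$ci[["upper"]],
    n_cases = sum(y == 1), n_controls = sum(y == 0),
    epv = ev$epv, epv_flagged = ev$flagged,
    scores = scores,
    pipeline = if (keep_model) pipeline else NULL),
    class = "discrimination_result")
}

#' Score a fitted pipeline on the geographic hold-out set
#'
#' The transform and model were fitted on discovery data only and are
#' applied unchanged. A single-class or empty hold-out yields a structured
#' warning and `NA` AUC.
#'
#' @param pipeline A `fitted_pipeline` (from [run_nested_cv()]).
#' @param cohort Cohort tibble.
#' @param holdout Tibble with `participant_id` and `role` columns.
#' @param bootstrap_B,seed Bootstrap settings.
#' @return List with `auc` and `ci`.
#' @export
evaluate_holdout <- function(pipeline, cohort, holdout, bootstrap_B = 1000,
                             seed = 1L) {
  empty <- list(auc = NA_real_, ci = c(lower = NA_real_, upper = NA_real_))
  if (nrow(holdout) == 0) {
    rlang::warn("empty hold-out set; AUC omitted")
    return(empty)
  }
  yh <- as.integer(holdout$role == "case")
  if (length(unique(yh)) < 2) {
    rlang::warn("single-class hold-out set; AUC omitted")
    return(empty)
  }
  rows <- match(holdout$participant_id, cohort$participant_id)
  xh <- apply_transform(pipeline$transform, cohort[rows, , drop = FALSE])
  pr <- predict_model(pipeline$model, xh)
  list(auc = roc_auc(pr$margin, yh),
       ci = bootstrap_auc_ci(pr$margin, yh, B = bootstrap_B, seed = seed))
}

#' Re-evaluate the harness on a restricted metabolite subset
#'
#' Runs the identical nested-CV harness with the feature set restricted to
#' `subset`, and reports the AUC difference against a full-feature result
#' when one is supplied.
#'
#' @param cohort,frame,spec,plan As in [run_nested_cv()].
#' @param subset Character vector of metabolite features (non-empty, all
#'   within the retained metabolite universe).
#' @param full_result Optional `discrimination_result` of the full
#'   metabolites-only run for the paired `delta_auc`.
#' @param ... Passed to [run_nested_cv()].
#' @return A `discrimination_result` with a `delta_auc` element.
#' @export
evaluate_feature_subset <- function(cohort, frame, spec, plan, subset,
                                    full_result = NULL, ...) {
  assert_that(length(subset) >= 1, "feature subset is empty")
  universe <- filter_missingness(cohort, 0.20, metabolite_features(cohort))
  bad <- setdiff(subset, universe)
  assert_that(length(bad) == 0,
              paste0("subset features outside the retained metabolite ",
                     "universe: ", paste(bad, collapse = ", ")))
  res <- run_nested_cv(cohort, frame, spec, plan, features = subset, ...)
  res$delta_auc <- if (!is.null(full_result)) {
    res$pooled_auc - full_result$pooled_auc
  } else NA_real_
  res
}

#' @export
tidy.discrimination_result <- function(x, ...) {
  tibble::tibble(phenotype = x$phenotype, algorithm = x$algorithm,
                 feature_set = x$feature_set, pooled_auc = x$pooled_auc,
                 ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                 mean_fold_auc = mean(x$fold_auc),
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 balanced_accuracy = x$balanced_accuracy,
                 holdout_auc = x$holdout_auc,
                 holdout_ci_lower = x$holdout_ci_lower,
                 holdout_ci_upper = x$holdout_ci_upper,
                 n_cases = x$n_cases, n_controls = x$n_controls,
                 epv = x$epv, epv_flagged = x$epv_flagged)
}

#' @export
glance.discrimination_result <- function(x, ...) {
  tibble::tibble(pooled_auc = x$pooled_auc, ci_lower = x$ci_lower,
                 ci_upper = x$ci_upper, epv = x$epv,
                 epv_flagged = x$epv_flagged)
}

#' Forest-style AUC plot for a set of discrimination results
#' @param object A list of `discrimination_result`s (or a tibble of tidied
#'   rows).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_discrimination <- function(object, ...) {
  df <- if (is.data.frame(object)) object else
    dplyr::bind_rows(purrr::map(object, tidy))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pooled_auc,
                                   y = .data$phenotype,
                                   color = .data$algorithm)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower,
                                         xmax = .data$ci_upper),
                            height = 0.2,
                            position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "pooled AUC (95% bootstrap CI)", y = NULL) +
    ggplot2::theme_minimal()
}
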