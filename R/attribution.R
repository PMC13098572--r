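#' Shapley-style per-feature attributions for a fitted pipeline
#'
#' Additive per-sample attributions satisfying local accuracy: for every
#' sample, baseline + sum of feature attributions equals the model's margin.
#' Linear models use the exact closed form
#' `coefficient_j * (x_j - baseline mean_j)`; gradient-boosted trees use the
#' exact tree-path decomposition (TreeSHAP); random forests fall back to an
#' interventional sampling estimator whose residual is distributed equally
#' across features to restore additivity — such tables are flagged
#' `approximate`.
#'
#' @param pipeline A `fitted_pipeline` (from [run_nested_cv()] with
#'   `keep_model = TRUE`), or an internal `atlas_model` plus pre-transformed
#'   matrices.
#' @param data Data frame of cohort rows to explain (transformed internally
#'   when `pipeline` is a `fitted_pipeline`).
#' @param baseline Data frame of baseline rows (default: `data`); the
#'   baseline value is the expected model margin over these rows.
#' @param n_perm Permutations per sample for the sampling fallback.
#' @param seed Seed for the sampling fallback.
#' @return An `attribution_table`: list with the per-sample `shap` matrix,
#'   `baseline` value, a `summary` tibble (`feature`, `mean_abs_attr`,
#'   `direction`), and flags.
#' @export
compute_attributions <- function(pipeline, data, baseline = NULL,
                                 n_perm = 8, seed = 1L) {
  if (inherits(pipeline, "fitted_pipeline")) {
    x <- apply_transform(pipeline$transform, data)
    bx <- if (is.null(baseline)) x else
      apply_transform(pipeline$transform, baseline)
    model <- pipeline$model
    feature_set <- pipeline$spec$feature_set
  } else {
    model <- pipeline
    x <- as.matrix(data)
    bx <- if (is.null(baseline)) x else as.matrix(baseline)
    feature_set <- NA_character_
  }
  assert_that(nrow(bx) > 0, "baseline data is empty")
  feats <- colnames(x)
  approximate <- FALSE
  if (model$algorithm == "logistic") {
    cf <- as.matrix(coef(model$fit, s = model$params$lambda))
    beta <- cf[-1, 1][feats]
    beta[is.na(beta)] <- 0
    bmean <- colMeans(bx)
    shap <- sweep(x, 2, bmean, `-`) %*% diag(beta, length(beta))
    colnames(shap) <- feats
    base <- cf[1, 1] + sum(beta * bmean)
  } else if (model$algorithm == "xgboost") {
    ctr <- predict(model$fit, xgboost::xgb.DMatrix(x), predcontrib = TRUE)
    base <- ctr[1, ncol(ctr)]
    shap <- ctr[, seq_len(ncol(ctr) - 1), drop = FALSE]
    colnames(shap) <- feats
  } else {
    approximate <- TRUE
    shap <- sampling_shapley(model, x, bx, n_perm = n_perm, seed = seed)
    base <- mean(predict_model(model, bx)$margin)
    marg <- predict_model(model, x)$margin
    resid <- marg - base - rowSums(shap)
    shap <- shap + resid / ncol(shap)   # restore additivity exactly
  }
  direction <- vapply(feats, function(f) {
    if (sd(x[, f]) == 0 || sd(shap[, f]) == 0) return(0)
    sign(cor(x[, f], shap[, f]))
  }, numeric(1))
  structure(list(shap = shap, baseline = base,
                 summary = tibble::tibble(feature = feats,
                                          mean_abs_attr = colMeans(abs(shap)),
                                          direction = unname(direction)),
                 algorithm = model$algorithm, feature_set = feature_set,
                 approximate = approximate),
            class = "attribution_table")
}

# interventional Monte-Carlo permutation Shapley estimate
sampling_shapley <- function(model, x, bx, n_perm, seed) {
  d <- ncol(x)
  shap <- matrix(0, nrow(x), d, dimnames = dimnames(x))
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      ord <- sample(d)
      ref <- bx[sample(nrow(bx), nrow(x), replace = TRUE), , drop = FALSE]
      cur <- ref
      prev <- predict_model(model, cur)$margin
      for (j in ord) {
        cur[, j] <- x[, j]
        now <- predict_model(model, cur)$margin
        shap[, j] <- shap[, j] + (now - prev)
        prev <- now
      }
    }
  })
  shap / n_perm
}

#' Top-k features of an attribution table
#'
#' Descending mean absolute attribution; ties broken lexicographically by
#' feature name and flagged.
#'
#' @param table An `attribution_table` (or its `summary` tibble).
#' @param k Number of features (default 30); if fewer exist, all are
#'   returned with a warning.
#' @return Tibble `feature`, `mean_abs_attr`, `direction`, `rank`.
#' @export
top_k_features <- function(table, k = 30) {
  s <- if (inherits(table, "attribution_table")) table$summary else table
  if (nrow(s) < k) {
    rlang::warn(sprintf("only %d features available for top-%d", nrow(s), k))
    k <- nrow(s)
  }
  s <- dplyr::arrange(s, dplyr::desc(.data$mean_abs_attr), .data$feature)
  if (k < nrow(s) && s$mean_abs_attr[k] == s$mean_abs_attr[k + 1]) {
    rlang::inform(sprintf("tie at rank %d broken lexicographically", k))
  }
  dplyr::mutate(utils::head(s, k), rank = dplyr::row_number())
}

#' Recurrence-based cross-disease consensus feature selection
#'
#' Counts, for every feature, the phenotypes in whose top-`k` attribution
#' ranking it appears; direction consistency is the largest fraction of
#' those phenotypes sharing one attribution sign. Selected features must
#' meet both thresholds. Invariant to phenotype ordering.
#'
#' @param tables Named list of `attribution_table`s, one per phenotype.
#' @param k Top-k membership threshold (default 30).
#' @param n_min Minimum recurrence count (default 10).
#' @param c_min Minimum direction consistency (default 0.8).
#' @return A `consensus_feature_set`: tibble `feature`, `recurrence`,
#'   `direction_consistency`, `selected`, with parameters as attributes.
#' @export
consensus_select <- function(tables, k = 30, n_min = 10, c_min = 0.8) {
  assert_that(length(tables) >= n_min,
              sprintf("need at least n_min = %d phenotype tables", n_min))
  assert_that(!is.null(names(tables)) && !anyNA(names(tables)),
              "`tables` must be named by phenotype")
  tk <- purrr::imap(tables, function(tb, p) {
    dplyr::mutate(top_k_features(tb, k), phenotype = p)
  }) |> dplyr::bind_rows()
  out <- tk |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      recurrence = dplyr::n(),
      direction_consistency = max(sum(.data$direction > 0),
                                  sum(.data$direction < 0)) / dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(selected = .data$recurrence >= n_min &
                    .data$direction_consistency >= c_min) |>
    dplyr::arrange(dplyr::desc(.data$recurrence), .data$feature)
  structure(out, k = k, n_min = n_min, c_min = c_min,
            n_phenotypes = length(tables),
            class = c("consensus_feature_set", class(out)))
}

#' Sankey edge table linking consensus features to phenotypes
#'
#' One row per (feature, phenotype) where the feature is both selected by
#' the consensus and in the phenotype's top-k; the weight is the source
#' table's mean absolute attribution (no renormalization). Only
#' combined-model attribution tables are admitted, matching the convention
#' that flow diagrams use combined (metabolites + clinical) model outputs.
#'
#' @param tables Named list of `attribution_table`s (combined models).
#' @param consensus A `consensus_feature_set`.
#' @param metadata Optional tibble `phenotype`, `category`.
#' @return Tibble `feature`, `phenotype`, `weight`, `feature_kind`,
#'   `phenotype_category`.
#' @export
sankey_edges <- function(tables, consensus, metadata = NULL) {
  keep <- purrr::map_lgl(tables, function(tb)
    is.na(tb$feature_set) || identical(tb$feature_set, "combined"))
  if (!all(keep)) {
    rlang::inform(sprintf("dropping %d non-combined attribution table(s)",
                          sum(!keep)))
    tables <- tables[keep]
  }
  sel <- consensus$feature[consensus$selected]
  k <- attr(consensus, "k")
  purrr::imap(tables, function(tb, p) {
    tk <- suppressMessages(top_k_features(tb, k))
    tk <- dplyr::filter(tk, .data$feature %in% sel)
    tibble::tibble(feature = tk$feature, phenotype = p,
                   weight = tk$mean_abs_attr,
                   feature_kind = ifelse(grepl("^met_", tk$feature),
                                         "metabolite", "clinical"))
  }) |>
    dplyr::bind_rows() |>
    dplyr::left_join(
      metadata %||% tibble::tibble(phenotype = character(),
                                   category = character()),
      by = "phenotype") |>
    dplyr::rename(phenotype_category = "category")
}

#' Write a consensus feature set as single-column text with metadata header
#' @param consensus A `consensus_feature_set`.
#' @param path File path.
#' @return Invisibly, the path.
#' @export
write_consensus <- function(consensus, path) {
  hdr <- sprintf("# k=%d n_min=%d c_min=%g n_phenotypes=%d",
                 attr(consensus, "k"), attr(consensus, "n_min"),
                 attr(consensus, "c_min"), attr(consensus, "n_phenotypes"))
  writeLines(c(hdr, consensus$feature[consensus$selected]), path)
  invisible(path)
}

#' Fit combined models and run consensus selection across phenotypes
#'
#' For each phenotype, builds a fold plan, runs the nested-CV harness with
#' the given spec(s), computes attributions for the best-performing spec
#' (highest pooled AUC), and feeds the per-phenotype tables into
#' [consensus_select()].
#'
#' @param cohort,frame As elsewhere.
#' @param specs A [model_spec()] or list of them (all should use the same
#'   feature set, normally `"combined"`).
#' @param seed Master seed (fold plans and attribution sampling derive from
#'   it).
#' @param phenotypes Phenotype codes (default: all in the frame).
#' @param k,n_min,c_min Consensus parameters.
#' @param max_explain Cap on rows used to compute attributions.
#' @param bootstrap_B Bootstrap iterations passed to the harness.
#' @return List with `results` (per phenotype x spec), `tables`
#'   (attribution tables of the best spec per phenotype) and `consensus`.
#' @export
run_consensus_study <- function(cohort, frame, specs, seed,
                                phenotypes = frame$phenotype,
                                k = 30, n_min = 10, c_min = 0.8,
                                max_explain = 500, bootstrap_B = 200) {
  if (inherits(specs, "model_spec")) specs <- list(specs)
  results <- list(); tables <- list()
  for (p in phenotypes) {
    plan <- make_fold_plan(cohort, frame, p,
                           seed = derive_seed(seed, paste0("plan_", p)))
    runs <- purrr::map(specs, function(sp)
      run_nested_cv(cohort, frame, sp, plan, keep_model = TRUE,
                    bootstrap_B = bootstrap_B))
    best <- runs[[which.max(purrr::map_dbl(runs, "pooled_auc"))]]
    rows <- match(plan$assign$participant_id, cohort$participant_id)
    if (length(rows) > max_explain) {
      rows <- with_seed(derive_seed(seed, paste0("explain_", p)),
                        sample(rows, max_explain))
    }
    tables[[p]] <- compute_attributions(best$pipeline,
                                        cohort[rows, , drop = FALSE],
                                        seed = derive_seed(seed, p))
    tables[[p]]$phenotype <- p
    results[[p]] <- runs
  }
  list(results = results, tables = tables,
       consensus = consensus_select(tables, k = k, n_min = n_min,
                                    c_min = c_min))
}
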