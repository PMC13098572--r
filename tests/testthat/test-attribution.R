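fit_small_pipeline <- function(algorithm, seed = 5, n = 400,
                               grid = default_grid(algorithm)[1]) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.4)
  m <- cbind(met_001 = y + rnorm(n, sd = 0.6),
             met_002 = rnorm(n),
             met_003 = 0.5 * y + rnorm(n))
  co <- dplyr::bind_cols(
    tibble::tibble(participant_id = sprintf("P%04d", 1:n),
                   region = "discovery", statin_flag = FALSE,
                   exclusion_flag = FALSE,
                   phenotype_codes = ifelse(y == 1, "C01.1", ".")),
    tibble::as_tibble(m))
  attr(co, "hierarchy") <- tibble::tibble(class_code = "C01",
                                          subclass_code = "C01.1")
  frame <- toy_frame(co)
  plan <- make_fold_plan(co, frame, "C01.1", seed = seed)
  sp <- model_spec(algorithm, "metabolites", grid = grid, seed = seed)
  r <- suppressWarnings(run_nested_cv(co, frame, sp, plan, bootstrap_B = 50,
                                      keep_model = TRUE))
  list(cohort = co, result = r)
}

margin_of <- function(pipeline, data) {
  x <- apply_transform(pipeline$transform, data)
  metaboatlas:::predict_model(pipeline$model, x)$margin
}

test_that("linear attributions are the exact closed form with local accuracy", {
  fx <- fit_small_pipeline("logistic")
  att <- compute_attributions(fx$result$pipeline, fx$cohort)
  marg <- margin_of(fx$result$pipeline, fx$cohort)
  expect_lt(max(abs(att$baseline + rowSums(att$shap) - marg)), 1e-6)
  # attribution_j = coefficient_j * (x_j - baseline mean_j), exactly
  x <- apply_transform(fx$result$pipeline$transform, fx$cohort)
  cf <- as.matrix(coef(fx$result$pipeline$model$fit, s = 0.01))
  beta <- cf[colnames(x), 1]
  expect_equal(att$shap,
               sweep(x, 2, colMeans(x)) %*% diag(beta) |>
                 `colnames<-`(colnames(x)),
               tolerance = 1e-10)
  expect_false(att$approximate)
})

test_that("tree attributions satisfy local accuracy and match exhaustive Shapley", {
  fx <- fit_small_pipeline("xgboost",
                           grid = list(list(nrounds = 50, max_depth = 3,
                                            eta = 0.2)))
  att <- compute_attributions(fx$result$pipeline, fx$cohort)
  marg <- margin_of(fx$result$pipeline, fx$cohort)
  # the tree-path decomposition is exact; the library evaluates it in single
  # precision, so the bound is relative to the margin scale
  err <- max(abs(att$baseline + rowSums(att$shap) - marg))
  expect_lt(err / max(1, max(abs(marg))), 1e-6)

  # single-split stump on two features: attribution concentrates on the
  # split feature; cross-check one sample against coalition enumeration
  set.seed(6)
  x <- cbind(a = rnorm(300), b = rnorm(300))
  y <- as.integer(x[, "a"] > 0)
  mod <- metaboatlas:::fit_model("xgboost", x, y, rep(1, 300),
                                 list(nrounds = 1, max_depth = 1, eta = 1), 1)
  att2 <- compute_attributions(mod, x)
  expect_lt(max(abs(att2$shap[, "b"])), 1e-9)
  predict_fn <- function(m) metaboatlas:::predict_model(mod, m)$margin
  phi <- oracle_shapley_2f(predict_fn, x[7, ], x)
  expect_equal(unname(att2$shap[7, ]), phi, tolerance = 1e-6)

  # constant features receive zero attribution
  x3 <- cbind(a = rnorm(200), b = rep(1, 200))
  y3 <- as.integer(x3[, "a"] > 0)
  mod3 <- metaboatlas:::fit_model("xgboost", x3, y3, rep(1, 200),
                                  list(nrounds = 5, max_depth = 2, eta = 0.5), 1)
  att3 <- compute_attributions(mod3, x3)
  expect_equal(max(abs(att3$shap[, "b"])), 0)
})

test_that("forest attributions are additivity-corrected and flagged approximate", {
  fx <- fit_small_pipeline("random_forest",
                           grid = list(list(num_trees = 50, max_depth = 4)))
  rows <- fx$cohort[1:60, ]
  att <- compute_attributions(fx$result$pipeline, rows, n_perm = 4, seed = 2)
  marg <- margin_of(fx$result$pipeline, rows)
  expect_true(att$approximate)
  expect_lt(max(abs(att$baseline + rowSums(att$shap) - marg)), 1e-8)
  # the informative feature dominates
  expect_gt(att$summary$mean_abs_attr[att$summary$feature == "met_001"],
            att$summary$mean_abs_attr[att$summary$feature == "met_002"])
})

fake_table <- function(values, directions = NULL) {
  f <- names(values)
  structure(list(summary = tibble::tibble(
    feature = f, mean_abs_attr = unname(values),
    direction = directions %||% rep(1, length(f))),
    feature_set = "combined", approximate = FALSE),
    class = "attribution_table")
}

test_that("top-k ranking is deterministic with lexicographic tie handling", {
  vals <- setNames(seq(40, 1), sprintf("f%02d", 1:40))
  tk <- top_k_features(fake_table(vals), 30)
  expect_equal(nrow(tk), 30)
  expect_equal(tk$feature[1], "f01")
  expect_warning(all_f <- top_k_features(fake_table(vals[1:5]), 30), "only 5")
  expect_equal(nrow(all_f), 5)
  tied <- setNames(c(3, 2, 2, 1), c("b", "a", "c", "d"))
  expect_message(tk2 <- top_k_features(fake_table(tied), 2), "tie")
  expect_equal(tk2$feature, c("b", "a"))
})

test_that("consensus selection enforces recurrence and direction thresholds", {
  feats <- sprintf("f%02d", 1:40)
  mk <- function(hot, dirs = 1) {
    v <- setNames(runif(40, 0, 0.1), feats)
    v[hot] <- 1
    fake_table(v, directions = ifelse(feats %in% hot, dirs, 1))
  }
  set.seed(1)
  # f01 in top-30 of 11/12 phenotypes, consistent sign -> selected;
  # f02 in 9/12 -> rejected at n_min = 10
  tables <- purrr::map(1:12, function(i) {
    mk(c(if (i <= 11) "f01", if (i <= 9) "f02"))
  })
  names(tables) <- paste0("P", 1:12)
  cs <- consensus_select(tables, k = 5, n_min = 10, c_min = 0.8)
  expect_true(cs$selected[cs$feature == "f01"])
  expect_equal(cs$recurrence[cs$feature == "f02"], 9)
  expect_false(cs$selected[cs$feature == "f02"])
  # inconsistent direction blocks selection
  tables2 <- purrr::map(1:12, function(i) mk("f01", dirs = (-1)^i))
  names(tables2) <- paste0("P", 1:12)
  cs2 <- consensus_select(tables2, k = 5, n_min = 10, c_min = 0.8)
  expect_false(cs2$selected[cs2$feature == "f01"])
  expect_lte(cs2$direction_consistency[cs2$feature == "f01"], 0.5)
  # invariant to phenotype ordering
  cs3 <- consensus_select(rev(tables), k = 5, n_min = 10, c_min = 0.8)
  expect_equal(as.data.frame(cs), as.data.frame(cs3))
  expect_error(consensus_select(tables[1:5], n_min = 10), "n_min")
})

test_that("null attributions give recurrence at the chance level", {
  feats <- sprintf("f%02d", 1:60)
  set.seed(33)
  P <- 12; k <- 10
  tables <- purrr::map(1:P, function(i)
    fake_table(setNames(runif(60), feats)))
  names(tables) <- paste0("P", 1:P)
  cs <- consensus_select(tables, k = k, n_min = 2, c_min = 0)
  counts <- setNames(rep(0, 60), feats)
  counts[cs$feature] <- cs$recurrence
  expect_equal(mean(counts), P * k / 60)  # exact by construction
  # every count inside a 99.9% binomial envelope around k/M
  bounds <- qbinom(c(5e-4, 1 - 5e-4), P, k / 60)
  expect_true(all(counts >= bounds[1] & counts <= bounds[2]))
})

test_that("sankey edges keep combined models only and source-table weights", {
  feats <- sprintf("f%02d", 1:10)
  t1 <- fake_table(setNames(10:1, feats))
  t2 <- fake_table(setNames(c(10, 9, rep(1, 7), 8), feats))
  t3 <- fake_table(setNames(10:1, feats)); t3$feature_set <- "metabolites"
  tables <- list(A = t1, B = t2, C = t3)
  cs <- consensus_select(list(A = t1, B = t2), k = 3, n_min = 2, c_min = 0)
  expect_message(edges <- sankey_edges(tables, cs,
                                       metadata = tibble::tibble(
                                         phenotype = c("A", "B"),
                                         category = "grp")),
                 "non-combined")
  expect_false("C" %in% edges$phenotype)
  # no edge for a feature outside a phenotype's top-k
  expect_setequal(unique(edges$phenotype), c("A", "B"))
  sel <- cs$feature[cs$selected]
  expect_true(all(edges$feature %in% sel))
  a_edge <- edges[edges$phenotype == "A", ]
  expect_equal(a_edge$weight,
               t1$summary$mean_abs_attr[match(a_edge$feature,
                                              t1$summary$feature)])
  expect_true(all(edges$phenotype_category == "grp"))
})
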