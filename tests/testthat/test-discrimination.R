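# small labeled cohort whose first metabolite optionally encodes the label
label_cohort <- function(n_case = 60, n_ctrl = 240, informative = TRUE,
                         seed = 1) {
  set.seed(seed)
  y <- c(rep(1, n_case), rep(0, n_ctrl))
  m <- cbind(met_001 = if (informative) y else rnorm(n_case + n_ctrl),
             met_002 = rnorm(n_case + n_ctrl),
             met_003 = rnorm(n_case + n_ctrl))
  co <- dplyr::bind_cols(
    tibble::tibble(participant_id = sprintf("P%04d", seq_along(y)),
                   region = "discovery", statin_flag = FALSE,
                   exclusion_flag = FALSE,
                   phenotype_codes = ifelse(y == 1, "C01.1", ".")),
    tibble::as_tibble(m),
    tibble::tibble(clin_01 = rnorm(n_case + n_ctrl)))
  attr(co, "hierarchy") <- tibble::tibble(class_code = "C01",
                                          subclass_code = "C01.1")
  co
}

test_that("roc_auc equals pair counting, the Mann-Whitney identity, and pROC", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.9, 0.4, 0.7, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(rep(0.3, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  set.seed(4)
  for (i in 1:10) {
    s <- round(rnorm(30), 1)  # ties likely
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), oracle_auc(s, y))
    # Mann-Whitney identity: U / (n1 n0)
    w <- suppressWarnings(wilcox.test(s[y == 1], s[y == 0]))
    expect_equal(roc_auc(s, y),
                 unname(w$statistic) / (sum(y == 1) * sum(y == 0)))
    # anti-symmetry
    expect_equal(roc_auc(-s, y), 1 - roc_auc(s, y))
  }
  skip_if_not_installed("pROC")
  set.seed(9)
  s <- rnorm(100); y <- rbinom(100, 1, 0.5)
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("bootstrap CI is seeded, degenerate for perfect separation", {
  y <- rep(c(1, 0), each = 250)
  s <- y + rnorm(500, sd = 0.01)
  ci <- bootstrap_auc_ci(s, y, B = 200, seed = 3)
  expect_lt(ci[["upper"]] - ci[["lower"]], 0.01)
  expect_equal(ci, bootstrap_auc_ci(s, y, B = 200, seed = 3))
  set.seed(1)
  s2 <- y + rnorm(500)   # overlapping scores: resamples actually vary
  expect_false(identical(bootstrap_auc_ci(s2, y, B = 200, seed = 3),
                         bootstrap_auc_ci(s2, y, B = 200, seed = 4)))
})

test_that("EPV flags low events-per-variable settings", {
  f1 <- epv_flag(100, 325, threshold = 5)
  expect_equal(f1$epv, 100 / 325, tolerance = 1e-12)
  expect_true(f1$flagged)
  f2 <- epv_flag(5000, 21, threshold = 5)
  expect_false(f2$flagged)
  expect_false(epv_flag(1, 1000, threshold = 0)$flagged)
})

test_that("a label-valued feature yields pooled AUC 1 for all three algorithms", {
  co <- label_cohort(informative = TRUE)
  frame <- toy_frame(co)
  plan <- make_fold_plan(co, frame, "C01.1", seed = 2)
  for (alg in c("logistic", "random_forest", "xgboost")) {
    sp <- model_spec(alg, "metabolites",
                     grid = default_grid(alg)[1], seed = 5)
    r <- suppressWarnings(run_nested_cv(co, frame, sp, plan,
                                        bootstrap_B = 50))
    expect_equal(r$pooled_auc, 1.0, tolerance = 1e-9)
  }
})

test_that("nested CV is deterministic and leakage-proof", {
  co <- label_cohort(informative = TRUE, seed = 2)
  frame <- toy_frame(co)
  plan <- make_fold_plan(co, frame, "C01.1", seed = 7)
  sp <- model_spec("logistic", "metabolites", seed = 11)
  r1 <- suppressWarnings(run_nested_cv(co, frame, sp, plan,
                                       bootstrap_B = 50, keep_model = TRUE))
  r2 <- suppressWarnings(run_nested_cv(co, frame, sp, plan,
                                       bootstrap_B = 50, keep_model = TRUE))
  expect_equal(r1$scores, r2$scores)
  expect_equal(r1$chosen_config, r2$chosen_config)

  # corrupt rows outside the fold plan (a fake holdout region participant)
  co3 <- label_cohort(informative = TRUE, seed = 2)
  co3$region[299] <- "holdout_A"   # move a control out of discovery
  frame3 <- toy_frame(co3)
  plan3 <- make_fold_plan(co3, frame3, "C01.1", seed = 7)
  co3_corrupt <- co3
  hid <- plan3$holdout$participant_id
  co3_corrupt[co3_corrupt$participant_id %in% hid,
              c("met_001", "met_002", "met_003")] <- 1e6
  ra <- suppressWarnings(run_nested_cv(co3, frame3, sp, plan3,
                                       bootstrap_B = 50, keep_model = TRUE))
  rb <- suppressWarnings(run_nested_cv(co3_corrupt, frame3, sp, plan3,
                                       bootstrap_B = 50, keep_model = TRUE))
  expect_equal(ra$scores, rb$scores)
  expect_identical(ra$pipeline$transform, rb$pipeline$transform)
  expect_equal(ra$chosen_config, rb$chosen_config)
})

test_that("holdout evaluation warns on empty or single-class sets", {
  co <- label_cohort()
  frame <- toy_frame(co)
  plan <- make_fold_plan(co, frame, "C01.1", seed = 2)
  sp <- model_spec("logistic", "metabolites", grid = list(list(lambda = 0.1)),
                   seed = 5)
  expect_warning(r <- run_nested_cv(co, frame, sp, plan, bootstrap_B = 50),
                 "empty hold-out")
  expect_true(is.na(r$holdout_auc))
})

test_that("holdout performance tracks discovery under exchangeability", {
  fix <- default_atlas_fixture()
  sp <- model_spec("logistic", "metabolites", grid = list(list(lambda = 0.1)),
                   seed = 31)
  plan <- make_fold_plan(fix$cohort, fix$frame, "C01", seed = 31)
  r <- run_nested_cv(fix$cohort, fix$frame, sp, plan, bootstrap_B = 100)
  expect_false(is.na(r$holdout_auc))
  expect_lt(abs(r$pooled_auc - r$holdout_auc), 0.05)
})

test_that("feature-subset evaluation is an identity on the full set and errors on empty", {
  co <- label_cohort(informative = TRUE, seed = 3)
  frame <- toy_frame(co)
  plan <- make_fold_plan(co, frame, "C01.1", seed = 4)
  sp <- model_spec("logistic", "metabolites", grid = list(list(lambda = 0.1)),
                   seed = 6)
  full <- suppressWarnings(run_nested_cv(co, frame, sp, plan,
                                         bootstrap_B = 50))
  sub <- suppressWarnings(evaluate_feature_subset(
    co, frame, sp, plan, subset = c("met_001", "met_002", "met_003"),
    full_result = full, bootstrap_B = 50))
  expect_equal(sub$pooled_auc, full$pooled_auc)
  expect_equal(sub$delta_auc, 0)
  expect_error(evaluate_feature_subset(co, frame, sp, plan, character()),
               "empty")
  expect_error(evaluate_feature_subset(co, frame, sp, plan, "met_999"),
               "met_999")
  # phenotype-irrelevant subset is uninformative
  noise <- suppressWarnings(evaluate_feature_subset(
    co, frame, sp, plan, subset = c("met_002", "met_003"),
    bootstrap_B = 50))
  expect_lt(abs(noise$pooled_auc - 0.5), 0.12)
})

test_that("combined models beat metabolites-only when clinical signal is independent", {
  fix <- default_atlas_fixture()
  grid1 <- list(list(nrounds = 60, max_depth = 3, eta = 0.1))
  aucs <- vapply(c("metabolites", "combined"), function(fs) {
    sp <- model_spec("xgboost", fs, grid = grid1, seed = 17)
    plan <- make_fold_plan(fix$cohort, fix$frame, "C03.1", seed = 17)
    run_nested_cv(fix$cohort, fix$frame, sp, plan, bootstrap_B = 50)$pooled_auc
  }, numeric(1))
  # C03.1 is a null-group phenotype: only the clinical covariates carry signal
  expect_gt(aucs["combined"], aucs["metabolites"])
})
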