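# Shared fixtures, cached per test run (cohort generation is the slow part).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the desk-scale atlas cohort: 3 planted phenotype groups (lipid-shared,
# renal-like gradient, null), ~330 cases per subclass, no statin effect
atlas_config <- function(seed, statin_effect = 0, shared_shift = 1.0) {
  generator_config(n_participants = 5200, n_metabolites = 60,
                   n_clinical = 20, n_classes = 3, subclasses_per_class = 2,
                   case_fraction_per_phenotype = 0.07,
                   shared_signature_size = 20, renal_signature_size = 10,
                   specific_size = 5, shared_shift = shared_shift,
                   specific_shift = 0.8, block_corr = 0.5, n_blocks = 9,
                   statin_effect = statin_effect, missing_rate = 0.05,
                   seed = seed)
}

assembled_atlas_cohort <- function(seed, statin_effect = 0) {
  co <- generate_cohort(atlas_config(seed, statin_effect))
  ex <- apply_exclusions(co)
  frame <- suppressMessages(build_phenotype_frame(ex$cohort, min_cases = 100))
  list(cohort = ex$cohort, frame = frame, ledger = ex$ledger, raw = co)
}

default_atlas_fixture <- function() {
  cached("atlas_fix", assembled_atlas_cohort(401))
}

# pure-noise cohort for null/leakage checks: one balanced contrast
null_config <- function(seed, n = 2000) {
  generator_config(n_participants = n, n_metabolites = 40, n_clinical = 10,
                   n_classes = 1, subclasses_per_class = 1,
                   case_fraction_per_phenotype = 0.5,
                   shared_signature_size = 5, renal_signature_size = 2,
                   specific_size = 2, shared_shift = 0, specific_shift = 0,
                   clinical_shift = 0, statin_effect = 0,
                   missing_rate = 0.02, missing_all_rate = 0,
                   exclusion_flag_rate = 0, seed = seed)
}

# build a disease_profiles-shaped tibble directly from a meanZ matrix
# (phenotypes x features), bypassing cohort machinery
profiles_from_matrix <- function(m, tau = 0.5) {
  df <- tibble::as_tibble(m, rownames = "phenotype") |>
    tidyr::pivot_longer(-phenotype, names_to = "feature",
                        values_to = "mean_z") |>
    dplyr::mutate(level = "class", n_cases = 10L,
                  altered = abs(mean_z) > tau)
  structure(df, tau = tau, features = colnames(m), n_controls = 100L,
            class = c("disease_profiles", class(df)))
}

# minimal hand-built cohort: one subclass contrast, explicit feature values
toy_cohort <- function(case_values, control_values, extra_features = NULL,
                       code = "C01.1") {
  if (is.vector(case_values)) case_values <- matrix(case_values, ncol = 1)
  if (is.vector(control_values)) control_values <- matrix(control_values, ncol = 1)
  k <- ncol(case_values)
  feats <- sprintf("met_%03d", seq_len(k))
  m <- rbind(case_values, control_values)
  colnames(m) <- feats
  n <- nrow(m)
  df <- dplyr::bind_cols(
    tibble::tibble(
      participant_id = sprintf("P%04d", seq_len(n)),
      region = "discovery", statin_flag = FALSE, exclusion_flag = FALSE,
      phenotype_codes = c(rep(code, nrow(case_values)),
                          rep(".", nrow(control_values)))),
    tibble::as_tibble(m))
  if (!is.null(extra_features)) df <- dplyr::bind_cols(df, extra_features)
  attr(df, "hierarchy") <- tibble::tibble(class_code = "C01",
                                          subclass_code = "C01.1")
  df
}

toy_frame <- function(cohort, min_cases = 1) {
  suppressMessages(build_phenotype_frame(cohort, min_cases = min_cases))
}

`%||%` <- rlang::`%||%`
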