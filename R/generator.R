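#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set for [generate_cohort()]. The
#' generator emulates an NMR-metabolomics case-control cohort: right-skewed
#' (log-normal) metabolite panels with block-correlated lipid groups, a
#' class/subclass disease hierarchy with planted mean-shift profiles
#' (a shared "cross-disease" signature for a lipid-driven phenotype group, a
#' second signature for a renal-like group, and an unshifted null group), a
#' statin-like medication flag that additively perturbs lipid features on the
#' log scale, completely-at-random missingness, and three region labels
#' (one discovery region plus two hold-out regions).
#'
#' All planted shifts are expressed in units of the control log-scale SD and
#' applied on the log scale, so the expected raw-scale mean z-score of a
#' planted feature has the closed form \eqn{(e^{\delta\sigma}-1)/\sqrt{e^{\sigma^2}-1}}
#' for shift \eqn{\delta} (SD units) and log-SD \eqn{\sigma}; see
#' [planted_meanz()].
#'
#' @param n_participants Number of participants.
#' @param n_metabolites Number of metabolite features (default 325).
#' @param n_clinical Number of clinical covariates (default 66).
#' @param n_classes Number of disease classes.
#' @param subclasses_per_class Subclasses under each class.
#' @param case_fraction_per_phenotype Fraction of participants assigned as
#'   cases of each subclass (subclass case sets are disjoint).
#' @param shared_signature_size Number of planted shared (lipid) signature
#'   features.
#' @param renal_signature_size Number of planted features shared by the
#'   renal-like phenotype group.
#' @param specific_size Phenotype-private planted features per subclass
#'   (lipid and renal groups only).
#' @param shared_shift,specific_shift Planted effect sizes in control
#'   log-scale SD units.
#' @param block_corr Within-block correlation of the log-metabolite blocks,
#'   in `[0, 1)`.
#' @param n_blocks Number of metabolite blocks (biomarker-group analogue).
#' @param log_sd Log-scale SD of every metabolite.
#' @param log_mean Log-scale baseline mean.
#' @param statin_effect Signed additive log-scale shift (SD units) applied to
#'   lipid-block features of statin-flagged participants; negative lowers
#'   them.
#' @param statin_prevalence_cases,statin_prevalence_controls Statin-flag
#'   prevalences by case status.
#' @param clinical_signal_size Number of clinical covariates carrying a case
#'   shift.
#' @param clinical_shift Case shift (SD units) on signal clinical covariates.
#' @param missing_rate MCAR missingness rate for metabolite and clinical
#'   values.
#' @param missing_all_rate Fraction of participants lacking all metabolite
#'   values (exclusion-stage fodder).
#' @param exclusion_flag_rate Fraction of participants carrying the generic
#'   exclusion flag (cancer-history analogue).
#' @param region_weights Named length-3 proportions for
#'   `discovery`, `holdout_A`, `holdout_B`; must sum to 1.
#' @param seed Integer seed; every random draw flows from it.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_participants = 2000,
                             n_metabolites = 325,
                             n_clinical = 66,
                             n_classes = 3,
                             subclasses_per_class = 2,
                             case_fraction_per_phenotype = 0.03,
                             shared_signature_size = 20,
                             renal_signature_size = 10,
                             specific_size = 5,
                             shared_shift = 1.0,
                             specific_shift = 0.8,
                             block_corr = 0.5,
                             n_blocks = 9,
                             log_sd = 0.25,
                             log_mean = 1.0,
                             statin_effect = -0.5,
                             statin_prevalence_cases = 0.3626,
                             statin_prevalence_controls = 0.0677,
                             clinical_signal_size = 5,
                             clinical_shift = 0.5,
                             missing_rate = 0.05,
                             missing_all_rate = 0.02,
                             exclusion_flag_rate = 0.02,
                             region_weights = c(discovery = 0.9,
                                                holdout_A = 0.05,
                                                holdout_B = 0.05),
                             seed) {
  if (missing(seed)) rlang::abort("generator_config(): `seed` must be given explicitly")
  cfg <- as.list(environment())
  for (p in c("case_fraction_per_phenotype", "statin_prevalence_cases",
              "statin_prevalence_controls", "missing_rate", "missing_all_rate",
              "exclusion_flag_rate")) {
    assert_that(is_prop(cfg[[p]]), paste0("`", p, "` must be a proportion in [0, 1]"))
  }
  assert_that(is.numeric(block_corr) && block_corr >= 0 && block_corr < 1,
              "`block_corr` must lie in [0, 1)")
  assert_that(length(region_weights) == 3 && all(region_weights >= 0) &&
                abs(sum(region_weights) - 1) < 1e-9,
              "`region_weights` must be 3 non-negative proportions summing to 1")
  names(cfg$region_weights) <- c("discovery", "holdout_A", "holdout_B")
  assert_that(shared_signature_size <= n_metabolites,
              "`shared_signature_size` cannot exceed `n_metabolites`")
  assert_that(log_sd > 0, "`log_sd` must be positive")
  n_sub <- n_classes * subclasses_per_class
  groups <- rep(c("lipid", "renal", "null"), length.out = n_classes)
  n_planting <- sum(groups != "null") * subclasses_per_class
  total_planted <- shared_signature_size + renal_signature_size +
    specific_size * n_planting
  if (total_planted > n_metabolites) {
    rlang::abort(sprintf(
      "planted features (%d shared + %d renal + %d x %d specific = %d) exceed n_metabolites = %d",
      shared_signature_size, renal_signature_size, specific_size, n_planting,
      total_planted, n_metabolites))
  }
  assert_that(case_fraction_per_phenotype * n_sub < 0.9,
              "subclass case fractions sum to >=0.9 of the cohort; reduce them")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "generator_config")
}

# class/subclass hierarchy implied by a config
config_hierarchy <- function(config) {
  classes <- sprintf("C%02d", seq_len(config$n_classes))
  tidyr::expand_grid(class_code = classes,
                     sub = seq_len(config$subclasses_per_class)) |>
    dplyr::mutate(subclass_code = sprintf("%s.%d", .data$class_code, .data$sub)) |>
    dplyr::select("class_code", "subclass_code")
}

#' Generate a synthetic cohort
#'
#' Draws a cohort with the structure described in [generator_config()].
#' Ground truth (planted shifts, phenotype group labels, feature block
#' membership) is attached as the `"ground_truth"` attribute; the disease
#' hierarchy as `"hierarchy"`; feature-name bookkeeping as `"features"`.
#' Fully reproducible from `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A `cohort_tbl` tibble, one row per participant, with columns
#'   `participant_id`, `region`, `statin_flag`, `exclusion_flag`,
#'   `phenotype_codes` (`"."` for controls), `planted_profile`, and the
#'   metabolite (`met_*`) and clinical (`clin_*`) feature columns.
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "generator_config"),
              "`config` must come from generator_config()")
  c_ <- config
  with_seed(c_$seed, {
    n <- c_$n_participants
    ids <- sprintf("P%06d", seq_len(n))
    hier <- config_hierarchy(c_)
    classes <- unique(hier$class_code)
    groups <- setNames(rep(c("lipid", "renal", "null"), length.out = c_$n_classes),
                       classes)
    subs <- hier$subclass_code
    sub_group <- setNames(groups[hier$class_code], subs)

    # feature bookkeeping -------------------------------------------------
    met <- sprintf("met_%03d", seq_len(c_$n_metabolites))
    block <- rep(seq_len(c_$n_blocks), length.out = c_$n_metabolites)
    block <- sort(block)  # contiguous blocks of near-equal size
    n_lipid_blocks <- max(1L, round(c_$n_blocks * 4 / 9))
    lipid <- block <= n_lipid_blocks
    lipid_idx <- which(lipid)
    assert_that(length(lipid_idx) >= c_$shared_signature_size,
                "lipid blocks too small to host the shared signature")
    shared_f <- met[lipid_idx[seq_len(c_$shared_signature_size)]]
    nonlipid_idx <- which(!lipid)
    assert_that(length(nonlipid_idx) >= c_$renal_signature_size,
                "non-lipid blocks too small to host the renal signature")
    renal_f <- met[nonlipid_idx[seq_len(c_$renal_signature_size)]]
    pool <- setdiff(met, c(shared_f, renal_f))
    planting_subs <- subs[sub_group[subs] != "null"]
    specific_f <- list()
    for (s in planting_subs) {
      specific_f[[s]] <- pool[seq_len(c_$specific_size)]
      pool <- pool[-seq_len(c_$specific_size)]
    }

    # case assignment (disjoint subclass case sets) -----------------------
    n_cases_per <- round(c_$case_fraction_per_phenotype * n)
    perm <- sample(n)
    codes <- rep(".", n)
    planted <- rep(NA_character_, n)
    pos <- 1L
    for (s in subs) {
      idx <- perm[pos:(pos + n_cases_per - 1L)]
      codes[idx] <- s
      planted[idx] <- s
      pos <- pos + n_cases_per
    }
    is_case <- codes != "."

    region <- sample(names(c_$region_weights), n, replace = TRUE,
                     prob = c_$region_weights)
    statin <- rbinom(n, 1, ifelse(is_case, c_$statin_prevalence_cases,
                                  c_$statin_prevalence_controls)) == 1
    excl <- rbinom(n, 1, c_$exclusion_flag_rate) == 1
    no_nmr <- rbinom(n, 1, c_$missing_all_rate) == 1

    # log-scale metabolite matrix -----------------------------------------
    sig <- c_$log_sd
    eps <- matrix(rnorm(n * c_$n_metabolites), n, c_$n_metabolites)
    u <- matrix(rnorm(n * c_$n_blocks), n, c_$n_blocks)
    L <- c_$log_mean +
      sig * (sqrt(c_$block_corr) * u[, block, drop = FALSE] +
               sqrt(1 - c_$block_corr) * eps)
    colnames(L) <- met

    shift_log <- matrix(0, length(subs), c_$n_metabolites,
                        dimnames = list(subs, met))
    for (s in subs) {
      g <- sub_group[[s]]
      if (g == "lipid") shift_log[s, shared_f] <- c_$shared_shift * sig
      if (g == "renal") shift_log[s, renal_f] <- c_$shared_shift * sig
      if (g != "null") shift_log[s, specific_f[[s]]] <- c_$specific_shift * sig
    }
    for (s in subs) {
      idx <- which(planted == s)
      if (length(idx)) L[idx, ] <- sweep(L[idx, , drop = FALSE], 2,
                                         shift_log[s, ], `+`)
    }
    statin_f <- met[lipid_idx]
    if (any(statin) && c_$statin_effect != 0) {
      L[statin, statin_f] <- L[statin, statin_f] + c_$statin_effect * sig
    }
    X <- exp(L)

    # clinical covariates --------------------------------------------------
    clin <- sprintf("clin_%02d", seq_len(c_$n_clinical))
    Z <- matrix(rnorm(n * c_$n_clinical), n, c_$n_clinical,
                dimnames = list(NULL, clin))
    sig_clin <- clin[seq_len(min(c_$clinical_signal_size, c_$n_clinical))]
    Z[is_case, sig_clin] <- Z[is_case, sig_clin] + c_$clinical_shift

    # missingness ----------------------------------------------------------
    if (c_$missing_rate > 0) {
      X[matrix(runif(length(X)) < c_$missing_rate, nrow(X))] <- NA
      Z[matrix(runif(length(Z)) < c_$missing_rate, nrow(Z))] <- NA
    }
    X[no_nmr, ] <- NA

    cohort <- dplyr::bind_cols(
      tibble::tibble(participant_id = ids, region = region,
                     statin_flag = statin, exclusion_flag = excl,
                     phenotype_codes = codes, planted_profile = planted),
      tibble::as_tibble(X), tibble::as_tibble(Z))

    gt <- list(
      config = c_,
      phenotype_groups = dplyr::bind_rows(
        tibble::tibble(phenotype = classes, level = "class",
                       group = unname(groups[classes])),
        tibble::tibble(phenotype = subs, level = "subclass",
                       group = unname(sub_group[subs]))),
      shift_log = shift_log, log_sd = sig, log_mean = c_$log_mean,
      feature_blocks = tibble::tibble(feature = met, block = block,
                                      lipid = lipid),
      shared_features = shared_f, renal_features = renal_f,
      specific_features = specific_f, statin_features = statin_f)

    new_cohort(cohort, hierarchy = hier,
               features = list(metabolite = met, clinical = clin),
               ground_truth = gt)
  })
}

new_cohort <- function(df, hierarchy, features, ground_truth = NULL) {
  structure(tibble::as_tibble(df), hierarchy = hierarchy, features = features,
            ground_truth = ground_truth,
            class = c("cohort_tbl", class(tibble::tibble())))
}

#' Expected raw-scale mean z-scores implied by the planted ground truth
#'
#' For a log-normal control distribution with log-SD \eqn{\sigma} and a case
#' shift of \eqn{d} on the log scale, the control-standardized raw-scale mean
#' z-score is exactly \eqn{(e^{d}-1)/\sqrt{e^{\sigma^2}-1}}. Valid as stated
#' when the statin effect is zero (otherwise statin mixing perturbs both
#' groups and the value is approximate).
#'
#' @param cohort A synthetic cohort carrying ground truth.
#' @return Tibble with `phenotype`, `feature`, `expected_meanz` for the
#'   planted subclasses.
#' @export
planted_meanz <- function(cohort) {
  gt <- attr(cohort, "ground_truth")
  assert_that(!is.null(gt), "cohort carries no ground truth")
  sig <- gt$log_sd
  sl <- gt$shift_log
  tibble::as_tibble(sl, rownames = "phenotype") |>
    tidyr::pivot_longer(-"phenotype", names_to = "feature",
                        values_to = "shift_log") |>
    dplyr::mutate(expected_meanz = (exp(.data$shift_log) - 1) /
                    sqrt(exp(sig^2) - 1))
}

#' Write / read a cohort as tab-separated text
#'
#' Missing values are written as the explicit sentinel `NA`; control rows
#' carry `"."` in `phenotype_codes`. `read_cohort()` validates the header,
#' participant-id uniqueness, and that every phenotype code exists in the
#' hierarchy, naming the offending row or code in its error.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @param hierarchy Hierarchy tibble (`class_code`, `subclass_code`); when
#'   reading, defaults to the hierarchy stored alongside via
#'   [write_hierarchy()] conventions is not assumed — pass it explicitly.
#' @return `read_cohort()` returns a `cohort_tbl`.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(cohort, path, na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, hierarchy) {
  hdr <- names(readr::read_tsv(path, n_max = 0, show_col_types = FALSE))
  known_types <- list(participant_id = readr::col_character(),
                      region = readr::col_character(),
                      phenotype_codes = readr::col_character(),
                      planted_profile = readr::col_character(),
                      statin_flag = readr::col_logical(),
                      exclusion_flag = readr::col_logical())
  spec <- do.call(readr::cols,
                  c(known_types[intersect(names(known_types), hdr)],
                    list(.default = readr::col_double())))
  df <- readr::read_tsv(path, na = "NA", col_types = spec,
                        show_col_types = FALSE, progress = FALSE)
  req <- c("participant_id", "region", "statin_flag", "phenotype_codes")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    rlang::abort(paste0("malformed cohort header: missing column(s) ",
                        paste(miss, collapse = ", ")))
  }
  dup <- df$participant_id[duplicated(df$participant_id)]
  if (length(dup)) {
    rlang::abort(paste0("duplicated participant_id: ",
                        paste(unique(dup), collapse = ", ")))
  }
  known <- c(hierarchy$class_code, hierarchy$subclass_code)
  codes <- setdiff(unlist(strsplit(df$phenotype_codes[df$phenotype_codes != "."],
                                   ";", fixed = TRUE)), known)
  if (length(codes)) {
    rlang::abort(paste0("phenotype code(s) absent from hierarchy: ",
                        paste(codes, collapse = ", ")))
  }
  new_cohort(df, hierarchy = hierarchy,
             features = list(metabolite = grep("^met_", names(df), value = TRUE),
                             clinical = grep("^clin_", names(df), value = TRUE)))
}

#' @rdname write_cohort
#' @export
write_hierarchy <- function(hierarchy, path) {
  readr::write_tsv(hierarchy, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_hierarchy <- function(path) {
  h <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("class_code", "subclass_code"), names(h))
  if (length(miss)) {
    rlang::abort(paste0("malformed hierarchy header: missing ",
                        paste(miss, collapse = ", ")))
  }
  h
}
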