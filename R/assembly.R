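#' Exclusion criteria for cohort assembly
#'
#' @param require_metabolomics Drop participants whose metabolite panel is
#'   entirely missing.
#' @param exclude_flagged Drop participants carrying the generic exclusion
#'   flag (cancer-history analogue).
#' @param min_cases_per_phenotype Phenotypes with fewer cases than this are
#'   dropped from the phenotype frame (default 100; exactly 100 is retained).
#' @return An `exclusion_criteria` list.
#' @export
exclusion_criteria <- function(require_metabolomics = TRUE,
                               exclude_flagged = TRUE,
                               min_cases_per_phenotype = 100) {
  assert_that(min_cases_per_phenotype >= 1,
              "`min_cases_per_phenotype` must be >= 1")
  structure(list(require_metabolomics = isTRUE(require_metabolomics),
                 exclude_flagged = isTRUE(exclude_flagged),
                 min_cases_per_phenotype = as.integer(min_cases_per_phenotype)),
            class = "exclusion_criteria")
}

#' Apply exclusion criteria, keeping an auditable flow ledger
#'
#' Exclusions are applied in order: participants lacking all metabolite
#' values first, then flagged participants; a participant matching several
#' criteria is removed once, at the first applicable step.
#'
#' @param cohort A cohort tibble.
#' @param criteria An [exclusion_criteria()].
#' @return List with `cohort` (filtered) and `ledger` (tibble of
#'   `step`, `n_removed`, `n_remaining`).
#' @export
apply_exclusions <- function(cohort, criteria = exclusion_criteria()) {
  assert_that(inherits(criteria, "exclusion_criteria"),
              "`criteria` must come from exclusion_criteria()")
  steps <- list()
  cur <- cohort
  if (criteria$require_metabolomics) {
    met <- metabolite_features(cur)
    assert_that(length(met) > 0, "cohort has no metabolite columns")
    all_missing <- rowSums(!is.na(as.matrix(cur[met]))) == 0
    steps[["missing_metabolomics"]] <- which(all_missing)
    cur <- cur[!all_missing, , drop = FALSE]
  }
  if (criteria$exclude_flagged) {
    assert_that("exclusion_flag" %in% names(cur),
                "criteria reference `exclusion_flag` but the cohort lacks it")
    flagged <- cur$exclusion_flag %in% TRUE
    steps[["exclusion_flag"]] <- which(flagged)
    cur <- cur[!flagged, , drop = FALSE]
  }
  ledger <- flow_ledger(nrow(cohort),
                        vapply(steps, length, integer(1)))
  if (nrow(cur) == 0) rlang::warn("all participants excluded")
  list(cohort = cur, ledger = ledger)
}

#' Build a cohort-flow ledger from an initial count and removal steps
#'
#' @param initial Initial participant count.
#' @param removals Named numeric vector of per-step removal counts.
#' @return Ledger tibble (`step`, `n_removed`, `n_remaining`), starting with
#'   an `enrolled` row.
#' @export
flow_ledger <- function(initial, removals = numeric()) {
  rem <- initial - cumsum(c(0, unname(removals)))
  tibble::tibble(step = c("enrolled", names(removals)),
                 n_removed = c(0, unname(removals)),
                 n_remaining = rem)
}

#' Check that a flow ledger balances (and matches expected counts)
#'
#' @param ledger A ledger tibble from [flow_ledger()] or
#'   [apply_exclusions()].
#' @param expected Optional named list/vector of expected values to
#'   cross-check; names are matched against `final` (final `n_remaining`)
#'   or ledger step names (their `n_remaining`).
#' @return Invisibly, a tibble report of the checks; imbalance is an error.
#' @export
validate_flow_arithmetic <- function(ledger, expected = NULL) {
  assert_that(all(c("step", "n_removed", "n_remaining") %in% names(ledger)),
              "not a flow ledger")
  init <- ledger$n_remaining[1] + ledger$n_removed[1]
  final <- ledger$n_remaining[nrow(ledger)]
  if (any(diff(ledger$n_remaining) > 0)) {
    rlang::abort("flow ledger imbalance: n_remaining increases")
  }
  if (!isTRUE(all.equal(final, init - sum(ledger$n_removed)))) {
    rlang::abort(sprintf(
      "flow ledger imbalance: initial %d - removed %d != final %d",
      init, sum(ledger$n_removed), final))
  }
  if (any(ledger$n_remaining != init - cumsum(ledger$n_removed))) {
    rlang::abort("flow ledger imbalance: a step's arithmetic does not add up")
  }
  checks <- tibble::tibble(name = "balance", value = final, ok = TRUE)
  if (!is.null(expected)) {
    for (nm in names(expected)) {
      got <- if (nm == "final") final else {
        i <- match(nm, ledger$step)
        assert_that(!is.na(i), paste0("unknown ledger step `", nm, "`"))
        ledger$n_remaining[i]
      }
      ok <- got == expected[[nm]]
      if (!ok) rlang::abort(sprintf(
        "flow ledger mismatch at `%s`: got %d, expected %d",
        nm, got, as.integer(expected[[nm]])))
      checks <- dplyr::bind_rows(checks,
                                 tibble::tibble(name = nm, value = got, ok = ok))
    }
  }
  invisible(checks)
}

#' Build per-phenotype case/control contrasts
#'
#' One contrast per retained class and subclass. A class's cases are the
#' union of its subclasses' cases plus any directly-coded cases (superset
#' convention). Controls are the globally phenotype-free participants — a
#' single shared control pool. Phenotypes with fewer than `min_cases` cases
#' are dropped and logged in the `"dropped"` attribute.
#'
#' @param cohort A cohort tibble (post-exclusion).
#' @param hierarchy Hierarchy tibble; defaults to the cohort attribute.
#' @param min_cases Minimum case count to retain a phenotype.
#' @return A `phenotype_frame` tibble (`phenotype`, `level`, `n_cases`,
#'   `cases` list-column) with the shared control ids in the `"controls"`
#'   attribute.
#' @export
build_phenotype_frame <- function(cohort, hierarchy = attr(cohort, "hierarchy"),
                                  min_cases = 100) {
  assert_that(!is.null(hierarchy), "no hierarchy available")
  assert_that(!any(duplicated(hierarchy$subclass_code)),
              "hierarchy structural error: duplicated subclass codes")
  if (any(hierarchy$subclass_code %in% hierarchy$class_code)) {
    rlang::abort("hierarchy structural error: a code is both class and subclass")
  }
  code_list <- strsplit(cohort$phenotype_codes, ";", fixed = TRUE)
  code_list <- purrr::map(code_list, function(x) setdiff(x, "."))
  known <- unique(c(hierarchy$class_code, hierarchy$subclass_code))
  unknown <- setdiff(unique(unlist(code_list)), known)
  if (length(unknown)) {
    rlang::abort(paste0("phenotype code(s) absent from hierarchy: ",
                        paste(unknown, collapse = ", ")))
  }
  long <- tibble::tibble(participant_id = rep(cohort$participant_id,
                                              lengths(code_list)),
                         code = unlist(code_list))
  controls <- setdiff(cohort$participant_id, unique(long$participant_id))

  sub_cases <- long |>
    dplyr::filter(.data$code %in% hierarchy$subclass_code) |>
    dplyr::distinct()
  cls_direct <- long |>
    dplyr::filter(.data$code %in% hierarchy$class_code) |>
    dplyr::distinct()
  parent <- setNames(hierarchy$class_code, hierarchy$subclass_code)

  frame <- dplyr::bind_rows(
    tibble::tibble(phenotype = unique(hierarchy$class_code), level = "class"),
    tibble::tibble(phenotype = unique(hierarchy$subclass_code),
                   level = "subclass")) |>
    dplyr::mutate(cases = purrr::map2(.data$phenotype, .data$level, function(p, lv) {
      if (lv == "subclass") {
        sort(sub_cases$participant_id[sub_cases$code == p])
      } else {
        kids <- names(parent)[parent == p]
        sort(unique(c(sub_cases$participant_id[sub_cases$code %in% kids],
                      cls_direct$participant_id[cls_direct$code == p])))
      }
    }),
    n_cases = lengths(.data$cases))

  dropped <- dplyr::filter(frame, .data$n_cases < min_cases)
  if (nrow(dropped)) {
    rlang::inform(sprintf("dropping %d phenotype(s) under %d cases: %s",
                          nrow(dropped), min_cases,
                          paste(dropped$phenotype, collapse = ", ")))
  }
  frame <- dplyr::filter(frame, .data$n_cases >= min_cases)
  structure(frame, controls = controls,
            dropped = dplyr::select(dropped, "phenotype", "level", "n_cases"),
            class = c("phenotype_frame", class(frame)))
}

#' Control ids of a phenotype frame
#' @param frame A `phenotype_frame`.
#' @return Character vector of control participant ids.
#' @export
frame_controls <- function(frame) attr(frame, "controls")

#' Case ids of one phenotype
#' @param frame A `phenotype_frame`.
#' @param phenotype Phenotype code.
#' @return Character vector of case participant ids.
#' @export
frame_cases <- function(frame, phenotype) {
  i <- match(phenotype, frame$phenotype)
  assert_that(!is.na(i), paste0("unknown phenotype `", phenotype, "`"))
  frame$cases[[i]]
}
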