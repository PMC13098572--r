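#' Disease-wise mean z-score profiles
#'
#' For every phenotype in the frame, each retained feature is standardized by
#' the control mean and SD (so the null is centered at zero) and averaged
#' over that phenotype's cases. Features with `|meanZ|` strictly above `tau`
#' form the phenotype's altered set. By default values are median-imputed
#' (global median) before standardization; `impute = FALSE` computes
#' complete-case statistics per feature instead. Features with zero control
#' SD are skipped with a message.
#'
#' @param cohort Cohort tibble (post-exclusion).
#' @param frame A `phenotype_frame`.
#' @param tau Altered-set threshold on `|meanZ|` (default 0.5, strict `>`).
#' @param features Feature columns to profile; default: metabolite features
#'   passing [filter_missingness()] at 20%.
#' @param impute Impute missing values with the feature median before
#'   standardizing (default) or use complete-case statistics.
#' @param values Optional numeric matrix (rows aligned with `cohort`) to
#'   profile instead of the cohort columns — used for residualized analyses.
#' @return A `disease_profiles` tibble: `phenotype`, `level`, `feature`,
#'   `mean_z`, `altered`, with `tau`, per-phenotype case/control counts and
#'   the feature universe as attributes.
#' @export
compute_profiles <- function(cohort, frame, tau = 0.5, features = NULL,
                             impute = TRUE, values = NULL) {
  if (is.null(features)) {
    features <- filter_missingness(cohort, 0.20, metabolite_features(cohort))
  }
  if (is.null(values)) {
    m <- as.matrix(cohort[features])
    storage.mode(m) <- "double"
  } else {
    m <- values[, features, drop = FALSE]
  }
  rownames(m) <- cohort$participant_id
  controls <- intersect(frame_controls(frame), rownames(m))
  assert_that(length(controls) > 1, "need at least 2 controls")
  if (impute) {
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- median(m[, j], na.rm = TRUE)
    }
  }
  cm <- m[controls, , drop = FALSE]
  mu <- colMeans(cm, na.rm = TRUE)
  sdv <- apply(cm, 2, sd, na.rm = TRUE)
  bad <- is.na(sdv) | sdv == 0
  if (any(bad)) {
    rlang::inform(paste0("skipping zero-control-SD feature(s): ",
                         paste(features[bad], collapse = ", ")))
    m <- m[, !bad, drop = FALSE]; mu <- mu[!bad]; sdv <- sdv[!bad]
    features <- features[!bad]
  }
  z <- sweep(sweep(m, 2, mu, `-`), 2, sdv, `/`)
  out <- purrr::pmap(list(frame$phenotype, frame$level, frame$cases),
                     function(p, lv, cs) {
    cs <- intersect(cs, rownames(z))
    if (length(cs) == 0) rlang::abort(paste0("phenotype `", p, "` has no cases"))
    mz <- colMeans(z[cs, , drop = FALSE], na.rm = TRUE)
    tibble::tibble(phenotype = p, level = lv, feature = features,
                   mean_z = unname(mz), n_cases = length(cs))
  })
  prof <- dplyr::bind_rows(out) |>
    dplyr::mutate(altered = abs(.data$mean_z) > tau)
  assert_that(all(is.finite(prof$mean_z)), "non-finite meanZ encountered")
  structure(prof, tau = tau, features = features,
            n_controls = length(controls),
            class = c("disease_profiles", class(prof)))
}

#' @rdname compute_profiles
#' @param phenotype Single phenotype code.
#' @return `compute_profile()` returns the one-phenotype subset, same shape.
#' @export
compute_profile <- function(cohort, frame, phenotype, tau = 0.5,
                            features = NULL, impute = TRUE) {
  i <- match(phenotype, frame$phenotype)
  assert_that(!is.na(i), paste0("unknown phenotype `", phenotype, "`"))
  sub <- frame[i, ]
  attr(sub, "controls") <- frame_controls(frame)  # lost by subsetting
  compute_profiles(cohort, sub, tau = tau, features = features,
                   impute = impute)
}

#' Altered-metabolite sets of a profile table
#' @param profiles A `disease_profiles` tibble.
#' @return Named list of character vectors (altered features per phenotype).
#' @export
altered_sets <- function(profiles) {
  sp <- split(profiles, profiles$phenotype)
  purrr::map(sp, function(d) d$feature[d$altered])
}

#' Mann-Whitney U comparisons with Benjamini-Hochberg correction
#'
#' Two-sided Mann-Whitney U tests (tie-corrected normal approximation) of
#' each phenotype's cases against the shared controls, per metabolite, on the
#' observed (non-missing) raw values. BH adjustment is applied across all
#' phenotype-by-metabolite cells of the one call — the correction family is
#' recorded in the `"family_size"` attribute. Star codes follow the adjusted
#' p: `*` < 0.05, `**` < 0.01, `***` < 0.001.
#'
#' @param cohort Cohort tibble.
#' @param frame A `phenotype_frame`.
#' @param metabolites Metabolite columns to test (default: retained set).
#' @param phenotypes Phenotype codes (default: all in the frame).
#' @return Tibble `phenotype`, `feature`, `statistic` (U, case-vs-control
#'   pair count), `p_value`, `p_adjusted`, `stars`.
#' @export
mann_whitney_bh <- function(cohort, frame, metabolites = NULL,
                            phenotypes = frame$phenotype) {
  if (is.null(metabolites)) {
    metabolites <- filter_missingness(cohort, 0.20, metabolite_features(cohort))
  }
  m <- as.matrix(cohort[metabolites])
  storage.mode(m) <- "double"
  rownames(m) <- cohort$participant_id
  ctrl <- intersect(frame_controls(frame), rownames(m))
  rows <- purrr::map(phenotypes, function(p) {
    cs <- intersect(frame_cases(frame, p), rownames(m))
    purrr::map(metabolites, function(f) {
      x <- m[cs, f]; x <- x[!is.na(x)]
      y <- m[ctrl, f]; y <- y[!is.na(y)]
      assert_that(length(x) >= 1 && length(y) >= 1,
                  paste0("no observed values for ", p, " / ", f))
      if (length(unique(c(x, y))) == 1) {
        rlang::warn(paste0("all values tied for ", p, " / ", f, "; p = 1"))
        u <- length(x) * length(y) / 2
        pv <- 1
      } else {
        wt <- suppressWarnings(
          wilcox.test(x, y, exact = FALSE, correct = FALSE))
        u <- unname(wt$statistic)
        pv <- min(1, wt$p.value)
      }
      tibble::tibble(phenotype = p, feature = f, statistic = u, p_value = pv)
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(p_adjusted = p.adjust(.data$p_value, method = "BH"),
                  stars = dplyr::case_when(.data$p_adjusted < 0.001 ~ "***",
                                           .data$p_adjusted < 0.01 ~ "**",
                                           .data$p_adjusted < 0.05 ~ "*",
                                           TRUE ~ ""))
  structure(out, family_size = nrow(out))
}

#' Heatmap-style plot of disease profiles
#' @param object A `disease_profiles` tibble.
#' @param ... Unused.
#' @return A ggplot object (phenotype-by-feature tile map of meanZ).
#' @export
autoplot.disease_profiles <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$phenotype, y = .data$feature,
                                       fill = .data$mean_z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", name = "mean z") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   axis.text.y = ggplot2::element_blank())
}
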