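#' @importFrom rlang abort warn inform %||% hash .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_chr map_int imap map2 keep
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom stats median sd cor rnorm runif rbinom setNames quantile
#'   wilcox.test p.adjust coef predict lm.fit as.dist
#' @importFrom utils head tail
NULL

# local seeded evaluation that never disturbs the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a stream-specific 31-bit seed from a master seed and a label
derive_seed <- function(seed, label) {
  h <- substr(rlang::hash(list(as.integer(seed), as.character(label))), 1, 7)
  (strtoi(h, base = 16L) %% .Machine$integer.max) + 1L
}

assert_that <- function(cond, msg) if (!isTRUE(cond)) rlang::abort(msg)

is_prop <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1

#' Names of metabolite / clinical feature columns of a cohort
#'
#' @param cohort A cohort tibble as produced by [generate_cohort()] or
#'   [read_cohort()].
#' @return Character vector of column names.
#' @export
metabolite_features <- function(cohort) {
  f <- attr(cohort, "features")
  if (!is.null(f)) return(f$metabolite)
  grep("^met_", names(cohort), value = TRUE)
}

#' @rdname metabolite_features
#' @export
clinical_features <- function(cohort) {
  f <- attr(cohort, "features")
  if (!is.null(f)) return(f$clinical)
  grep("^clin_", names(cohort), value = TRUE)
}
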