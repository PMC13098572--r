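#' Jaccard overlap of two altered-metabolite sets
#'
#' `|A intersect B| / |A union B|`. Two empty sets are treated as identical
#' (similarity 1) and flagged via the `"degenerate"` attribute.
#'
#' @param a,b Character vectors (sets over the retained feature universe).
#' @return Numeric in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(structure(1, degenerate = TRUE))
  length(intersect(a, b)) / u
}

#' Spearman profile correlation rescaled to [0, 1]
#'
#' Average-rank Spearman correlation of two mean z-score profiles, mapped by
#' the affine rescale `(rho + 1) / 2`. A zero-variance profile is
#' uninformative: the midpoint 0.5 is returned, flagged.
#'
#' @param a,b Numeric profiles on the identical feature universe,
#'   length >= 3.
#' @return Numeric in `[0, 1]`.
#' @export
spearman_rescaled <- function(a, b) {
  if (length(a) != length(b)) rlang::abort("profile length mismatch")
  assert_that(length(a) >= 3, "profiles must have length >= 3")
  if (sd(a) == 0 || sd(b) == 0) return(structure(0.5, degenerate = TRUE))
  (cor(a, b, method = "spearman") + 1) / 2
}

#' Composite inter-disease similarity atlas
#'
#' For every phenotype pair the composite similarity
#' \eqn{S = \omega J + (1-\omega) R'} blends the Jaccard overlap \eqn{J} of
#' altered-metabolite sets with the rescaled Spearman correlation \eqn{R'} of
#' the mean z-score profiles. The dissimilarity \eqn{D = 1 - S} is clustered
#' by deterministic complete linkage.
#'
#' @param profiles A `disease_profiles` tibble ([compute_profiles()]).
#' @param omega Weight on the Jaccard component, in `[0, 1]` (default 0.5).
#' @return A `similarity_atlas`: list with `phenotypes`, matrices `J`, `R`,
#'   `S`, `D`, the `linkage` (dendrogram), `omega`, `tau`, and a `flags`
#'   tibble of degenerate pairs.
#' @export
composite_similarity <- function(profiles, omega = 0.5) {
  assert_that(is_prop(omega), "`omega` must lie in [0, 1]")
  sets <- altered_sets(profiles)
  wide <- profiles |>
    dplyr::select("phenotype", "feature", "mean_z") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "mean_z")
  ph <- wide$phenotype
  assert_that(length(ph) >= 2, "need at least 2 phenotypes")
  pm <- as.matrix(wide[-1])
  rownames(pm) <- ph
  n <- length(ph)
  J <- R <- diag(1, n)
  dimnames(J) <- dimnames(R) <- list(ph, ph)
  flags <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    jv <- jaccard(sets[[ph[i]]], sets[[ph[j]]])
    rv <- spearman_rescaled(pm[i, ], pm[j, ])
    if (isTRUE(attr(jv, "degenerate"))) {
      flags[[length(flags) + 1]] <- tibble::tibble(
        phenotype_a = ph[i], phenotype_b = ph[j], component = "jaccard")
    }
    if (isTRUE(attr(rv, "degenerate"))) {
      flags[[length(flags) + 1]] <- tibble::tibble(
        phenotype_a = ph[i], phenotype_b = ph[j], component = "spearman")
    }
    J[i, j] <- J[j, i] <- as.numeric(jv)
    R[i, j] <- R[j, i] <- as.numeric(rv)
  }
  S <- omega * J + (1 - omega) * R
  D <- 1 - S
  diag(D) <- 0
  structure(list(phenotypes = ph, J = J, R = R, S = S, D = D,
                 omega = omega, tau = attr(profiles, "tau"),
                 linkage = complete_linkage(D),
                 flags = dplyr::bind_rows(flags)),
            class = "similarity_atlas")
}

#' Deterministic complete-linkage agglomerative clustering
#'
#' Agglomerates at the maximum inter-cluster distance. Ties are broken by
#' the lexicographically smallest (cluster label) pair, where a cluster is
#' labeled by its smallest leaf label; leaf ordering is the recursive
#' subtree traversal with the smaller-labeled subtree first. Heights are
#' non-decreasing (complete linkage is monotone).
#'
#' @param D Symmetric dissimilarity matrix with labeled rows/columns.
#' @return A `linkage`: list with `labels`, `merges` (tibble `step`,
#'   `height`, `a`, `b` cluster labels, `members` list-column) and `order`
#'   (leaf labels in dendrogram order).
#' @export
complete_linkage <- function(D) {
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-12,
                        check.attributes = FALSE))) {
    rlang::abort("dissimilarity matrix is not symmetric")
  }
  labels <- rownames(D) %||% as.character(seq_len(nrow(D)))
  dimnames(D) <- list(labels, labels)
  n <- nrow(D)
  clusters <- as.list(labels)          # member leaf labels
  names(clusters) <- labels            # cluster label = min leaf label
  tree <- setNames(vector("list", n), labels)  # nested order structure
  for (l in labels) tree[[l]] <- l
  cd <- D                              # current complete-linkage distances
  merges <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    labs <- names(clusters)
    m <- length(labs)
    best <- NULL
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      d <- cd[labs[i], labs[j]]
      pair <- sort(c(labs[i], labs[j]))
      if (is.null(best) || d < best$d - 1e-12 ||
          (abs(d - best$d) <= 1e-12 &&
             (pair[1] < best$pair[1] ||
                (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
        best <- list(d = d, pair = pair)
      }
    }
    a <- best$pair[1]; b <- best$pair[2]
    members <- c(clusters[[a]], clusters[[b]])
    new_lab <- min(a, b)
    merges[[step]] <- tibble::tibble(step = step, height = best$d,
                                     a = a, b = b,
                                     members = list(sort(members)))
    # update distances: complete linkage = max
    others <- setdiff(names(clusters), c(a, b))
    newd <- if (length(others)) pmax(cd[a, others], cd[b, others]) else numeric()
    clusters[[new_lab]] <- members
    tree[[new_lab]] <- list(tree[[a]], tree[[b]])   # a < b: smaller first
    drop_lab <- setdiff(c(a, b), new_lab)
    clusters[[drop_lab]] <- NULL
    tree[[drop_lab]] <- NULL
    keep <- names(clusters)
    cd <- cd[keep, keep, drop = FALSE]
    if (length(others)) {
      cd[new_lab, others] <- newd
      cd[others, new_lab] <- newd
    }
  }
  order_rec <- function(node) {
    if (is.character(node)) return(node)
    c(order_rec(node[[1]]), order_rec(node[[2]]))
  }
  structure(list(labels = labels,
                 merges = dplyr::bind_rows(merges),
                 order = order_rec(tree[[1]])),
            class = "linkage")
}

#' Convert a linkage to a base-R hclust object
#' @param linkage A `linkage` from [complete_linkage()].
#' @return An `hclust` object (for plotting or Newick export).
#' @export
as_hclust <- function(linkage) {
  labels <- linkage$labels
  n <- length(labels)
  merge <- matrix(0L, n - 1, 2)
  cluster_step <- list()   # cluster label -> step that formed it
  for (s in seq_len(n - 1)) {
    row <- linkage$merges[s, ]
    enc <- function(lab) {
      if (!is.null(cluster_step[[lab]])) cluster_step[[lab]]
      else -match(lab, labels)
    }
    ea <- enc(row$a); eb <- enc(row$b)
    merge[s, ] <- sort(c(ea, eb))
    cluster_step[[min(row$a, row$b)]] <- s
  }
  structure(list(merge = merge, height = linkage$merges$height,
                 order = match(linkage$order, labels), labels = labels,
                 method = "complete", call = match.call(),
                 dist.method = "composite"),
            class = "hclust")
}

#' Cut a dendrogram into k clusters
#'
#' Removes the `k - 1` highest merges. A tie at the cut height is resolved
#' by merge order and flagged with a message and the `"tie"` attribute.
#'
#' @param linkage A `linkage`, or a `similarity_atlas` (its linkage is used).
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Tibble `phenotype`, `cluster` (integer labels, numbered by first
#'   appearance in label order).
#' @export
cut_partition <- function(linkage, k) {
  if (inherits(linkage, "similarity_atlas")) linkage <- linkage$linkage
  labels <- linkage$labels
  n <- length(labels)
  assert_that(k >= 1 && k <= n, "`k` must satisfy 1 <= k <= n")
  tie <- FALSE
  if (k > 1 && n - k >= 1) {
    h <- linkage$merges$height
    if (abs(h[n - k] - h[n - k + 1]) <= 1e-12) {
      tie <- TRUE
      rlang::inform("tie at cut height; resolved by merge order")
    }
  }
  parent <- setNames(labels, labels)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  if (n - k >= 1) for (s in seq_len(n - k)) {
    row <- linkage$merges[s, ]
    ra <- find(row$a); rb <- find(row$b)
    root <- min(ra, rb)
    parent[[ra]] <- root; parent[[rb]] <- root
  }
  roots <- vapply(labels, find, character(1))
  cl <- as.integer(factor(roots, levels = unique(roots)))
  structure(tibble::tibble(phenotype = labels, cluster = cl), tie = tie)
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement under the permutation model, computed from the
#' contingency table: `(Index - Expected) / (Max - Expected)`.
#'
#' @param a,b Partitions over the same items: cluster-label vectors (named
#'   vectors are aligned by name) or tibbles with `phenotype` and `cluster`
#'   columns as returned by [cut_partition()].
#' @return The ARI (1 for identical partitions; about 0 at chance).
#' @export
adjusted_rand_index <- function(a, b) {
  as_labels <- function(x) {
    if (is.data.frame(x)) setNames(x$cluster, x$phenotype) else x
  }
  a <- as_labels(a); b <- as_labels(b)
  if (!is.null(names(a)) && !is.null(names(b))) {
    assert_that(setequal(names(a), names(b)),
                "partitions cover different item sets")
    b <- b[names(a)]
  }
  assert_that(length(a) == length(b) && length(a) >= 2,
              "partitions must cover the same >= 2 items")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(length(a))
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < 1e-12) {
    return(if (abs(sum_ij - expected) < 1e-12) 1 else 0)
  }
  (sum_ij - expected) / (maxi - expected)
}

#' Residualize features on a statin-use indicator
#'
#' Per-feature least-squares regression on the statin indicator (optionally
#' plus covariates); residuals are z-standardized. With the indicator alone,
#' residual group means are exactly balanced across flag levels.
#'
#' @param cohort Cohort tibble (or any data frame with the feature columns).
#' @param features Feature columns to residualize (default: retained
#'   metabolites).
#' @param statin Logical vector; defaults to the cohort's `statin_flag`.
#' @param covariates Optional numeric matrix/data frame of extra covariates.
#' @return Numeric matrix of standardized residuals, rows aligned with
#'   `cohort`.
#' @export
statin_residualize <- function(cohort, features = NULL, statin = NULL,
                               covariates = NULL) {
  if (is.null(features)) {
    features <- filter_missingness(cohort, 0.20, metabolite_features(cohort))
  }
  if (is.null(statin)) statin <- cohort$statin_flag
  if (length(unique(statin)) < 2) {
    rlang::abort("statin flag has a single level; cannot residualize")
  }
  m <- as.matrix(cohort[features])
  storage.mode(m) <- "double"
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (any(nas)) m[nas, j] <- median(m[, j], na.rm = TRUE)
  }
  X <- cbind(intercept = 1, statin = as.numeric(statin))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  res <- lm.fit(X, m)$residuals
  res <- scale(res)
  colnames(res) <- features
  res[, , drop = FALSE]
}

#' Export an atlas dendrogram as Newick text
#' @param atlas A `similarity_atlas` (or a `linkage`).
#' @param path Optional file path.
#' @return The Newick string (invisibly when written to `path`).
#' @export
atlas_newick <- function(atlas, path = NULL) {
  lk <- if (inherits(atlas, "similarity_atlas")) atlas$linkage else atlas
  phy <- ape::as.phylo(as_hclust(lk))
  txt <- ape::write.tree(phy)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' @rdname composite_similarity
#' @param cohort,frame,tau,features,statin_adjust,covariates Convenience
#'   arguments: `build_atlas()` profiles the cohort (optionally on
#'   statin-residualized values) and builds the composite atlas in one call.
#' @export
build_atlas <- function(cohort, frame, tau = 0.5, omega = 0.5,
                        features = NULL, statin_adjust = FALSE,
                        covariates = NULL) {
  if (is.null(features)) {
    features <- filter_missingness(cohort, 0.20, metabolite_features(cohort))
  }
  values <- if (statin_adjust) {
    statin_residualize(cohort, features, covariates = covariates)
  } else NULL
  prof <- compute_profiles(cohort, frame, tau = tau, features = features,
                           values = values)
  composite_similarity(prof, omega = omega)
}

#' @export
tidy.similarity_atlas <- function(x, ...) {
  ph <- x$phenotypes
  idx <- which(upper.tri(x$S), arr.ind = TRUE)
  tibble::tibble(phenotype_a = ph[idx[, 1]], phenotype_b = ph[idx[, 2]],
                 jaccard = x$J[idx], spearman_rescaled = x$R[idx],
                 similarity = x$S[idx], dissimilarity = x$D[idx])
}

#' @export
glance.similarity_atlas <- function(x, ...) {
  tibble::tibble(n_phenotypes = length(x$phenotypes), omega = x$omega,
                 tau = x$tau,
                 mean_similarity = mean(x$S[upper.tri(x$S)]),
                 max_merge_height = max(x$linkage$merges$height),
                 n_degenerate_pairs = nrow(x$flags))
}

#' Heatmap of the composite similarity matrix in dendrogram leaf order
#' @param object A `similarity_atlas`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.similarity_atlas <- function(object, ...) {
  ord <- object$linkage$order
  df <- tidy(object) |>
    dplyr::mutate(phenotype_a = factor(.data$phenotype_a, levels = ord),
                  phenotype_b = factor(.data$phenotype_b, levels = ord))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phenotype_a,
                                   y = .data$phenotype_b,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "S") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write the atlas matrices as labeled square TSV files
#' @param atlas A `similarity_atlas`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in c("J", "R", "S", "D")) {
    p <- file.path(dir, paste0("atlas_", nm, ".tsv"))
    readr::write_tsv(tibble::as_tibble(atlas[[nm]], rownames = "phenotype"), p)
    paths <- c(paths, p)
  }
  nw <- file.path(dir, "atlas_dendrogram.nwk")
  atlas_newick(atlas, nw)
  invisible(c(paths, nw))
}
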