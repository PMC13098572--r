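# Independent brute-force oracles used to pin down the analytic machinery.
# These deliberately avoid the package's own code paths.

# pair-counting AUC: concordant pairs + half ties over all case/control pairs
oracle_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# classical BH step-up, written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) adj[i] <- min(sorted[i:m] * m / (i:m))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# pair-counting adjusted Rand index (independent of the contingency formula)
oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  num <- 2 * (n00 * n11 - n01 * n10)
  den <- (n00 + n01) * (n01 + n11) + (n00 + n10) * (n10 + n11)
  if (den == 0) return(if (n10 + n01 == 0) 1 else 0)
  num / den
}

# all partitions of n items as restricted-growth label vectors
oracle_partitions <- function(n) {
  out <- list()
  rec <- function(labels, next_lab) {
    i <- length(labels) + 1
    if (i > n) { out[[length(out) + 1]] <<- labels; return() }
    for (l in seq_len(next_lab)) {
      rec(c(labels, l), max(next_lab, l + 1))
    }
  }
  rec(integer(), 1)
  out
}

# brute-force complete-linkage agglomerator on a labeled dissimilarity
# matrix; inter-cluster distance recomputed from scratch over member pairs
oracle_complete_linkage <- function(D) {
  labels <- rownames(D)
  clusters <- as.list(labels)
  merges <- list()
  step <- 0
  while (length(clusters) > 1) {
    step <- step + 1
    best_d <- Inf; best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- max(D[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (d < best_d - 1e-12 ||
            (abs(d - best_d) <= 1e-12 && !is.null(best) &&
               (key[1] < best$key[1] ||
                  (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best_d <- d; best <- list(i = i, j = j, key = key)
        }
      }
    }
    members <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[step]] <- list(height = best_d, members = members)
    clusters[[best$i]] <- members
    clusters[[best$j]] <- NULL
  }
  merges
}

# partition from oracle merges: apply the first n - k merges
oracle_cut <- function(merges, labels, k) {
  cl <- setNames(labels, labels)
  n <- length(labels)
  if (n - k >= 1) for (s in seq_len(n - k)) {
    mem <- merges[[s]]$members
    cl[mem] <- min(cl[mem])
  }
  setNames(as.integer(factor(cl, levels = unique(cl))), labels)
}

# Spearman rho by the no-ties rank-difference formula
oracle_spearman <- function(a, b) {
  d <- rank(a) - rank(b)
  n <- length(a)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# exhaustive interventional Shapley values for a 2-feature model
oracle_shapley_2f <- function(predict_fn, x_row, baseline) {
  v <- function(S) {
    m <- baseline
    for (j in S) m[, j] <- x_row[j]
    mean(predict_fn(m))
  }
  phi1 <- 0.5 * ((v(1) - v(integer())) + (v(c(1, 2)) - v(2)))
  phi2 <- 0.5 * ((v(2) - v(integer())) + (v(c(1, 2)) - v(1)))
  c(phi1, phi2)
}
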