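test_that("Jaccard overlap handles identity, disjoint and degenerate sets", {
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(as.numeric(jaccard(c("a", "b"), c("a", "b"))), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  j <- jaccard(character(), character())
  expect_equal(as.numeric(j), 1)
  expect_true(attr(j, "degenerate"))
})

test_that("rescaled Spearman maps [-1, 1] onto [0, 1] with rank-formula values", {
  expect_equal(spearman_rescaled(c(1, 2, 3), c(3, 2, 1)), 0)
  expect_equal(spearman_rescaled(c(1, 5, 2, 9), c(1, 5, 2, 9)), 1)
  r <- spearman_rescaled(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(oracle_spearman(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_equal(r, 0.8)
  z <- spearman_rescaled(c(1, 1, 1), c(1, 2, 3))
  expect_equal(as.numeric(z), 0.5)
  expect_true(attr(z, "degenerate"))
  expect_error(spearman_rescaled(1:4, 1:5), "mismatch")
})

test_that("composite similarity is the stated blend with correct limits", {
  m <- rbind(A = c(2, 1, 0.1, -0.2), B = c(1.5, 0.8, 0.2, -0.1),
             C = c(-0.1, 0.2, 2, 1))
  colnames(m) <- paste0("f", 1:4)
  prof <- profiles_from_matrix(m)
  at <- composite_similarity(prof, omega = 0.5)
  expect_equal(at$S, 0.5 * at$J + 0.5 * at$R)
  expect_true(isSymmetric(at$S))
  expect_equal(unname(diag(at$S)), rep(1, 3))
  expect_true(all(at$S >= 0 & at$S <= 1))
  at_j <- composite_similarity(prof, omega = 1)
  expect_equal(at_j$S, at_j$J)
  at_r <- composite_similarity(prof, omega = 0)
  expect_equal(at_r$S, at_r$R)
  # identical profiles are maximally similar
  m2 <- rbind(A = c(2, 1, -1), B = c(2, 1, -1))
  colnames(m2) <- paste0("f", 1:3)
  at2 <- composite_similarity(profiles_from_matrix(m2))
  expect_equal(at2$S["A", "B"], 1)
})

test_that("increasing altered-set overlap never decreases S at fixed profiles", {
  base <- rbind(A = c(0.6, 0.7, 0.1, 0.2, 0.3),
                B = c(0.7, 0.1, 0.6, 0.3, 0.2))
  colnames(base) <- paste0("f", 1:5)
  p1 <- profiles_from_matrix(base)
  # grow overlap: make B's altered set include A's f2 too, same ranks
  p2 <- p1
  p2$altered[p2$phenotype == "B" & p2$feature == "f2"] <- TRUE
  s1 <- composite_similarity(p1)$S["A", "B"]
  s2 <- composite_similarity(p2)$S["A", "B"]
  expect_gte(s2, s1)
})

test_that("complete linkage reproduces the worked three-point dendrogram", {
  D <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.8, 0.9, 0.8, 0), 3, 3,
              dimnames = list(c("p1", "p2", "p3"), c("p1", "p2", "p3")))
  lk <- complete_linkage(D)
  expect_equal(lk$merges$height, c(0.1, 0.9))
  expect_equal(lk$merges$members[[1]], c("p1", "p2"))
  expect_equal(lk$merges$members[[2]], c("p1", "p2", "p3"))
  cut2 <- cut_partition(lk, 2)
  expect_equal(cut2$cluster, c(1, 1, 2))
  expect_equal(cut_partition(lk, 1)$cluster, rep(1, 3))
  expect_equal(cut_partition(lk, 3)$cluster, 1:3)

  # n = 2 and duplicate-point edge cases
  D2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2, dimnames = list(c("a", "b"),
                                                        c("a", "b")))
  expect_equal(complete_linkage(D2)$merges$height, 0.3)
  D3 <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D3) <- 0
  D3["a", "b"] <- D3["b", "a"] <- 0
  lk3 <- complete_linkage(D3)
  expect_equal(lk3$merges$height[1], 0)
  expect_equal(lk3$merges$members[[1]], c("a", "b"))
  expect_error(complete_linkage(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("complete linkage and cuts agree with brute-force oracles and hclust", {
  for (s in 1:40) {
    set.seed(s)
    n <- sample(3:7, 1)
    labs <- sprintf("L%02d", sample(20, n))
    D <- matrix(0, n, n, dimnames = list(labs, labs))
    D[upper.tri(D)] <- runif(n * (n - 1) / 2)
    D <- D + t(D)
    lk <- complete_linkage(D)
    orc <- oracle_complete_linkage(D)
    expect_equal(lk$merges$height, vapply(orc, `[[`, numeric(1), "height"))
    for (i in seq_along(orc)) {
      expect_equal(lk$merges$members[[i]], orc[[i]]$members)
    }
    # heights match stats::hclust as an independent implementation
    hc <- hclust(as.dist(D), method = "complete")
    expect_equal(sort(lk$merges$height), sort(hc$height))
    for (k in 1:n) {
      got <- cut_partition(lk, k)
      want <- oracle_cut(orc, labs, k)
      expect_equal(oracle_ari(got$cluster, want[got$phenotype]), 1)
    }
  }
})

test_that("ARI matches worked values and the pair-counting oracle exhaustively", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(adjusted_rand_index(1:4, rep(1, 4)), 0)
  parts <- oracle_partitions(5)
  for (a in parts) for (b in parts) {
    expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b))
  }
  skip_if_not_installed("mclust")
  set.seed(2)
  for (i in 1:20) {
    a <- sample(3, 8, replace = TRUE); b <- sample(3, 8, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
})

test_that("atlases are invariant to phenotype input order", {
  set.seed(14)
  m <- matrix(rnorm(5 * 12), 5, 12,
              dimnames = list(paste0("P", 1:5), paste0("f", 1:12)))
  m[1:2, 1:4] <- m[1:2, 1:4] + 1
  a1 <- composite_similarity(profiles_from_matrix(m))
  perm <- c(4, 2, 5, 1, 3)
  a2 <- composite_similarity(profiles_from_matrix(m[perm, ]))
  expect_equal(a2$S[rownames(a1$S), colnames(a1$S)], a1$S)
  expect_setequal(a2$linkage$order, a1$linkage$order)
  expect_equal(a2$linkage$merges$height, a1$linkage$merges$height)
})

test_that("statin residualization balances flag groups exactly", {
  set.seed(3)
  n <- 400
  flag <- rep(c(TRUE, FALSE), each = n / 2)
  co <- toy_cohort(matrix(rnorm(20), 10, 2),
                   matrix(rnorm(2 * (n - 10)), n - 10, 2))
  co$statin_flag <- flag
  co$met_001 <- co$met_001 - 2 * flag   # constant statin displacement
  res <- statin_residualize(co, c("met_001", "met_002"))
  expect_lt(abs(mean(res[flag, "met_001"]) - mean(res[!flag, "met_001"])),
            1e-8)
  expect_error(statin_residualize(co, statin = rep(TRUE, n)), "single level")
})

test_that("null-effect residualization converges to the centered original", {
  deltas <- vapply(c(200, 2000), function(n) {
    set.seed(n)
    x <- rnorm(n, 10)
    co <- toy_cohort(matrix(x[1:10], 10, 1), matrix(x[-(1:10)], n - 10, 1))
    co$statin_flag <- rep_len(c(TRUE, FALSE), n)
    res <- statin_residualize(co, "met_001")
    ctr <- as.vector(scale(x))
    max(abs(res[, "met_001"] - ctr))
  }, numeric(1))
  expect_lt(deltas[2], deltas[1])  # shrinks with n (null OLS coefficient)
  expect_lt(deltas[2], 0.1)
})

test_that("Newick export is a valid tree over the phenotype leaves", {
  m <- rbind(A = c(2, 1, 0.3), B = c(1.8, 0.9, 0.2), C = c(-1, 0.1, 2))
  colnames(m) <- paste0("f", 1:3)
  at <- composite_similarity(profiles_from_matrix(m))
  txt <- atlas_newick(at)
  phy <- ape::read.tree(text = txt)
  expect_setequal(phy$tip.label, c("A", "B", "C"))
  td <- tidy(at)
  expect_equal(nrow(td), 3)
  expect_named(glance(at),
               c("n_phenotypes", "omega", "tau", "mean_similarity",
                 "max_merge_height", "n_degenerate_pairs"))
  expect_s3_class(autoplot(at), "ggplot")
})
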