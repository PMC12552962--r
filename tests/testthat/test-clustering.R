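const_matrix <- function(n, off) {
  S <- matrix(off, n, n)
  diag(S) <- 1
  dimnames(S) <- list(sprintf("T%03d", 1:n), sprintf("T%03d", 1:n))
  S
}

test_that("binary cut accepts tight matrices and respects the cutoff boundary", {
  S <- const_matrix(6, 0.9)
  a <- binary_cut(S, cutoff = 0.85)
  expect_equal(a$n_clusters, 1)
  expect_equal(unname(a$labels), rep(1L, 6))
  # cutoff 0: root node always accepted
  rough <- synth_similarity(c(4, 4), seed = 5)
  expect_equal(binary_cut(rough$S, cutoff = 0)$n_clusters, 1)
})

test_that("binary cut recovers planted blocks exactly", {
  fx <- synth_similarity(c(4, 4), within_range = c(0.8, 0.95),
                         between_range = c(0, 0.2), seed = 7)
  a <- binary_cut(fx$S, cutoff = 0.85)
  expect_equal(a$n_clusters, 2)
  expect_equal(ari(a$labels[names(fx$labels)], fx$labels), 1)
  # same plant, k-means partitioner
  ak <- binary_cut(fx$S, cutoff = 0.85, partitioner = "kmeans2")
  expect_equal(ari(ak$labels[names(fx$labels)], fx$labels), 1)
})

test_that("binary cut rejects broken matrices", {
  S <- const_matrix(4, 0.5)
  S[1, 2] <- 0.9                      # asymmetric
  expect_error(binary_cut(S), "not symmetric")
  S2 <- const_matrix(4, 0.5)
  S2[1, 2] <- S2[2, 1] <- 1.5
  expect_error(binary_cut(S2), "\\[0, 1\\]")
  S3 <- const_matrix(4, 0.5)
  diag(S3) <- 0.9
  expect_error(binary_cut(S3), "diagonal")
  expect_error(binary_cut(const_matrix(4, 0.2), cutoff = 2), "cutoff")
  expect_error(binary_cut(const_matrix(4, 0.2), min_split = 1), "min_split")
})

test_that("hierarchical clustering finds planted k by silhouette; k edge cases", {
  fx <- synth_similarity(c(5, 6, 4), seed = 11)
  a <- hierarchical_cluster(fx$S)
  expect_equal(a$n_clusters, 3)
  expect_equal(ari(a$labels[names(fx$labels)], fx$labels), 1)
  # silhouette maximum located by brute force over k must agree
  D <- as.dist(1 - fx$S)
  hc <- hclust(D, method = "average")
  sil <- sapply(2:14, function(k) {
    mean(cluster::silhouette(cutree(hc, k), D)[, "sil_width"])
  })
  expect_equal(a$n_clusters, (2:14)[which.max(sil)])

  n <- nrow(fx$S)
  expect_equal(hierarchical_cluster(fx$S, k = 1)$n_clusters, 1)
  expect_equal(hierarchical_cluster(fx$S, k = n)$n_clusters, n)
  expect_error(hierarchical_cluster(fx$S, k = n + 1), "k must lie")
})

test_that("combined equals binary cut when no refinement trigger fires", {
  fx <- synth_similarity(c(6, 5, 7), within_range = c(0.85, 0.95),
                         between_range = c(0, 0.1), seed = 13)
  b <- binary_cut(fx$S, cutoff = 0.8)
  cmb <- combined_cluster(fx$S, cutoff = 0.8, refine_threshold = 0.5,
                          max_cluster_size = 50)
  expect_identical(cmb$labels, b$labels)
  expect_identical(cmb$n_clusters, b$n_clusters)
})

test_that("combined splits a loose super-cluster into its planted sub-blocks", {
  # two 0.9-tight sub-blocks bridged at 0.3: binary cut at cutoff 0.5 accepts
  # the union (mean ~0.56), the combined method's refinement splits it
  fx <- synth_similarity(c(4, 4), within_range = c(0.88, 0.92),
                         between_range = c(0.28, 0.32), seed = 17)
  b <- binary_cut(fx$S, cutoff = 0.5)
  expect_equal(b$n_clusters, 1)
  cmb <- combined_cluster(fx$S, cutoff = 0.5, refine_threshold = 0.6)
  expect_equal(cmb$n_clusters, 2)
  expect_equal(ari(cmb$labels[names(fx$labels)], fx$labels), 1)
})

test_that("combined refinement of a loose pair yields singletons", {
  S <- const_matrix(2, 0.2)
  cmb <- combined_cluster(S, cutoff = 0.1, refine_threshold = 0.5)
  expect_equal(cmb$n_clusters, 2)
  expect_equal(unname(cmb$labels), c(1L, 2L))
})

test_that("oversized clusters trigger refinement regardless of tightness", {
  fx <- synth_similarity(c(5, 5), within_range = c(0.88, 0.92),
                         between_range = c(0.28, 0.32), seed = 19)
  cmb <- combined_cluster(fx$S, cutoff = 0.5, refine_threshold = 0,
                          max_cluster_size = 6)
  expect_equal(ari(cmb$labels[names(fx$labels)], fx$labels), 1)
})

test_that("every method labels every term exactly once", {
  for (seed in 1:5) {
    fx <- synth_similarity(c(4, 9, 6), seed = 20 + seed)
    for (a in list(binary_cut(fx$S, 0.7), hierarchical_cluster(fx$S),
                   combined_cluster(fx$S, 0.7))) {
      expect_setequal(names(a$labels), rownames(fx$S))
      expect_setequal(unique(unname(a$labels)), seq_len(a$n_clusters))
      expect_equal(length(a$labels), nrow(fx$S))
    }
  }
})

test_that("clustering is invariant to the row/column order of S", {
  fx <- synth_similarity(c(5, 7, 4), seed = 31)
  perm <- gocondense:::with_seed(32, sample(nrow(fx$S)))
  Sp <- fx$S[perm, perm]
  for (f in list(function(S) binary_cut(S, 0.7),
                 hierarchical_cluster,
                 function(S) combined_cluster(S, 0.7))) {
    a <- f(fx$S)
    ap <- f(Sp)
    expect_equal(ari(ap$labels[names(a$labels)], a$labels), 1)
  }
})

test_that("difference score: forced arithmetic, degenerate labels, oracle", {
  fx <- synth_similarity(c(4, 4), within_range = c(0.9, 0.9),
                         between_range = c(0.1, 0.1), seed = 3)
  a <- binary_cut(fx$S, cutoff = 0.85)
  expect_equal(difference_score(fx$S, a), 0.8)

  # constant matrix: any labeling scores 0
  S <- const_matrix(10, 0.4)
  lab <- gocondense:::with_seed(8, sample(1:3, 10, replace = TRUE))
  fake <- structure(list(labels = setNames(lab, rownames(S)),
                         n_clusters = 3L, method = "binary"),
                    class = "cluster_assignment")
  expect_equal(difference_score(S, fake), 0)

  one <- structure(list(labels = setNames(rep(1L, 10), rownames(S)),
                        n_clusters = 1L, method = "binary"),
                   class = "cluster_assignment")
  expect_error(difference_score(S, one), "fewer than 2")

  for (seed in 1:10) {
    fx <- synth_similarity(c(7, 6, 7), seed = 40 + seed)
    lab <- gocondense:::with_seed(seed, sample(1:4, 20, replace = TRUE))
    lab <- as.integer(factor(lab))   # dense indices
    fake <- structure(list(labels = setNames(lab, rownames(fx$S)),
                           n_clusters = max(lab), method = "binary"),
                      class = "cluster_assignment")
    if (max(lab) < 2) next
    expect_equal(difference_score(fx$S, fake),
                 oracle_difference_score(fx$S, lab), tolerance = 1e-12)
  }
})

test_that("benchmark tabulates scores and paired Wilcoxon statistics", {
  fx <- lapply(1:4, function(i) synth_similarity(c(5, 6), seed = 50 + i)$S)
  res <- benchmark_methods(fx, cutoff = 0.7)
  expect_equal(dim(res$scores), c(4, 4))
  expect_equal(names(res$scores), c("fixture", "binary", "hclust", "combined"))
  expect_equal(nrow(res$wilcoxon), 3)
  expect_error(benchmark_methods(fx[1]), "at least 2")

  # a broken fixture is skipped, not fatal
  bad <- const_matrix(4, 0.5); bad[1, 2] <- 2; bad[2, 1] <- 2
  res2 <- suppressMessages(benchmark_methods(c(fx, list(bad)), cutoff = 0.7))
  expect_equal(res2$skipped, 5)
  expect_equal(nrow(res2$scores), 4)

  # methods that agree exactly give a degenerate (p = 1) comparison
  tight <- lapply(1:3, function(i) {
    synth_similarity(c(5, 5), within_range = c(0.9, 0.95),
                     between_range = c(0, 0.05), seed = 60 + i)$S
  })
  res3 <- benchmark_methods(tight, cutoff = 0.7)
  bc <- res3$wilcoxon[res3$wilcoxon$pair == "binary vs combined", ]
  expect_true(bc$degenerate)
  expect_equal(bc$p_value, 1)
})

test_that("cluster assignments export as TSV", {
  fx <- synth_similarity(c(3, 3), seed = 71)
  a <- binary_cut(fx$S, 0.7)
  path <- tempfile(fileext = ".tsv")
  write_clusters_tsv(a, path)
  df <- read.delim(path)
  expect_equal(nrow(df), 6)
  expect_equal(names(df), c("term_id", "cluster", "method"))
})
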