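#' Binary cut clustering of a similarity matrix
#'
#' Recursive two-way partitioning. For the current submatrix `M` the node
#' score `s(M)` is the mean of its off-diagonal entries (a 1x1 submatrix
#' scores 1). If `s(M) >= cutoff`, or the submatrix is smaller than
#' `min_split`, its terms are emitted as one cluster; otherwise the terms are
#' partitioned into two groups by PAM or k-means (k = 2) applied to the rows
#' of `M` — each term's similarity profile is its feature vector — and each
#' group is processed recursively. The procedure is deterministic given the
#' parameters and seed.
#'
#' @param S Symmetric similarity matrix in `[0, 1]` with unit diagonal.
#' @param cutoff Accept-as-cluster threshold on the node score, in `[0, 1]`.
#'   The default 0.85 suits semantic-similarity matrices where genuinely
#'   redundant term groups are very tight; looser planted structure calls for
#'   a cutoff between the expected within- and between-cluster similarity.
#' @param partitioner `"pam2"` (default) or `"kmeans2"`.
#' @param min_split Smallest submatrix that may still be split (>= 2).
#' @param seed Integer seed for the partitioner.
#' @return A `cluster_assignment`: list with `labels` (named integer vector,
#'   dense 1-based cluster indices in order of first appearance), `n_clusters`
#'   and `method = "binary"`.
#' @export
binary_cut <- function(S, cutoff = 0.85, partitioner = c("pam2", "kmeans2"),
                       min_split = 2, seed = 1) {
  partitioner <- match.arg(partitioner)
  validate_similarity(S)
  if (cutoff < 0 || cutoff > 1) stop_input("cutoff must lie in [0, 1]")
  if (min_split < 2) stop_input("min_split must be >= 2")
  n <- nrow(S)
  if (n < 2) stop_input("binary cut needs at least 2 terms")

  groups <- list()
  recurse <- function(idx) {
    s <- node_score(S, idx)
    if (s >= cutoff || length(idx) < min_split) {
      groups[[length(groups) + 1L]] <<- idx
      return()
    }
    part <- split_two(S, idx, partitioner, seed)
    if (length(unique(part)) < 2) {      # degenerate split: stop here
      groups[[length(groups) + 1L]] <<- idx
      return()
    }
    recurse(idx[part == 1])
    recurse(idx[part == 2])
  }
  recurse(seq_len(n))
  as_cluster_assignment(groups, rownames(S), "binary")
}

# mean off-diagonal similarity of S[idx, idx]; 1 for a single item
node_score <- function(S, idx) {
  m <- length(idx)
  if (m == 1) return(1)
  M <- S[idx, idx, drop = FALSE]
  (sum(M) - m) / (m * (m - 1))
}

# Both partitioners operate on the rows of the submatrix: each term's
# similarity profile is its feature vector, so members of one block share a
# profile even when their pairwise distances to other blocks are noisy.
split_two <- function(S, idx, partitioner, seed) {
  if (length(idx) == 2) return(c(1L, 2L))  # PAM/k-means need k < n
  M <- S[idx, idx, drop = FALSE]
  if (partitioner == "pam2") {
    fit <- with_seed(seed, cluster::pam(M, k = 2, cluster.only = TRUE))
    unname(fit)
  } else {
    fit <- with_seed(seed, stats::kmeans(M, centers = 2, nstart = 5))
    unname(fit$cluster)
  }
}

# Normalize a list of index groups to dense labels ordered by each
# cluster's first member in input order (stable, deterministic).
as_cluster_assignment <- function(groups, ids, method) {
  first <- vapply(groups, min, numeric(1))
  groups <- groups[order(first)]
  labels <- integer(length(ids))
  for (k in seq_along(groups)) labels[groups[[k]]] <- k
  structure(list(labels = stats::setNames(labels, ids),
                 n_clusters = length(groups), method = method),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment (%s): %d terms in %d clusters\n",
              x$method, length(x$labels), x$n_clusters))
  invisible(x)
}

#' Agglomerative hierarchical clustering of a similarity matrix
#'
#' Clusters on the distance `1 - S`. When `k` is omitted it is chosen to
#' maximize the mean silhouette width over `k = 2 .. min(n - 1, 25)`, ties
#' going to the smallest `k`; with only two terms the degenerate choice is
#' `k = 2`.
#'
#' @param S Symmetric similarity matrix.
#' @param linkage `"average"` (default) or `"complete"`.
#' @param k Optional number of clusters (`1 <= k <= n`).
#' @return A `cluster_assignment` with `method = "hclust"`.
#' @export
hierarchical_cluster <- function(S, linkage = c("average", "complete"),
                                 k = NULL) {
  linkage <- match.arg(linkage)
  validate_similarity(S)
  n <- nrow(S)
  if (n < 2) stop_input("hierarchical clustering needs at least 2 terms")
  D <- stats::as.dist(1 - S)
  hc <- stats::hclust(D, method = linkage)
  if (is.null(k)) {
    ks <- seq(2, min(n - 1, 25))
    if (length(ks) == 0 || n == 2) {
      k <- 2L
    } else {
      sil <- vapply(ks, function(kk) {
        cl <- stats::cutree(hc, k = kk)
        mean(cluster::silhouette(cl, D)[, "sil_width"])
      }, numeric(1))
      k <- ks[which.max(sil)]          # which.max takes the first maximum
    }
  } else {
    if (k < 1 || k > n) stop_input("k must lie in 1..n (n = %d)", n)
  }
  cl <- if (k == 1) rep(1L, n) else stats::cutree(hc, k = k)
  groups <- split(seq_len(n), cl)
  as_cluster_assignment(unname(groups), rownames(S), "hclust")
}

#' Combined clustering: binary cut with hierarchical refinement
#'
#' Stage 1 runs [binary_cut()]. Stage 2 re-clusters every stage-1 cluster that
#' is *loose* (within-cluster mean off-diagonal similarity below
#' `refine_threshold`) or *oversized* (more members than `max_cluster_size`)
#' with [hierarchical_cluster()] restricted to its submatrix, the number of
#' sub-clusters chosen by silhouette. Tight, reasonably sized clusters pass
#' through unchanged, so on well-separated input the combined method equals
#' binary cut exactly.
#'
#' @inheritParams binary_cut
#' @param refine_threshold Within-cluster mean similarity below which a
#'   stage-1 cluster is refined. Default 0.5.
#' @param max_cluster_size Largest stage-1 cluster accepted without
#'   refinement. Default 50.
#' @return A `cluster_assignment` with `method = "combined"`.
#' @export
combined_cluster <- function(S, cutoff = 0.85,
                             partitioner = c("pam2", "kmeans2"),
                             min_split = 2, seed = 1,
                             refine_threshold = 0.5, max_cluster_size = 50) {
  partitioner <- match.arg(partitioner)
  stage1 <- binary_cut(S, cutoff = cutoff, partitioner = partitioner,
                       min_split = min_split, seed = seed)
  groups <- list()
  for (k in seq_len(stage1$n_clusters)) {
    idx <- which(stage1$labels == k)
    within <- node_score(S, idx)
    trigger <- (within < refine_threshold || length(idx) > max_cluster_size) &&
      length(idx) >= 2
    if (!trigger) {
      groups[[length(groups) + 1L]] <- unname(idx)
      next
    }
    sub <- hierarchical_cluster(S[idx, idx, drop = FALSE])
    for (kk in seq_len(sub$n_clusters)) {
      groups[[length(groups) + 1L]] <- unname(idx[sub$labels == kk])
    }
  }
  out <- as_cluster_assignment(groups, rownames(S), "combined")
  out
}

#' Cluster separation (difference score)
#'
#' `mean(S[i, j] : i < j in the same cluster) - mean(S[i, j] : i < j in
#' different clusters)`. Singleton clusters contribute no within-cluster
#' pairs; if every cluster is a singleton the within-cluster mean is defined
#' as 0. At least two clusters are required so the between-cluster pair set
#' is non-empty.
#'
#' @param S Symmetric similarity matrix.
#' @param assignment A `cluster_assignment` labeling every term of `S`.
#' @return The difference score (a real number in `[-1, 1]`).
#' @export
difference_score <- function(S, assignment) {
  validate_similarity(S)
  ids <- rownames(S)
  if (!setequal(names(assignment$labels), ids) ||
      length(assignment$labels) != length(ids)) {
    stop_input("assignment must label exactly the terms of S")
  }
  if (assignment$n_clusters < 2) {
    stop_input("difference score undefined for fewer than 2 clusters")
  }
  lab <- assignment$labels[ids]
  same <- outer(lab, lab, "==")
  up <- upper.tri(S)
  w <- S[up & same]
  b <- S[up & !same]
  within <- if (length(w) == 0) 0 else mean(w)
  within - mean(b)
}

#' Benchmark the three clustering methods on a set of fixtures
#'
#' Runs binary cut, hierarchical clustering and the combined method on each
#' similarity matrix, tabulates the difference scores, and reports paired
#' Wilcoxon signed-rank tests between each pair of methods. Fixtures that
#' fail the similarity-matrix contract are skipped and listed.
#'
#' @param fixtures List of similarity matrices (>= 2).
#' @param cutoff,partitioner,min_split,seed Passed to the binary-cut stage.
#' @param refine_threshold,max_cluster_size Passed to the combined method.
#' @return List with `scores` (data.frame: `fixture`, `binary`, `hclust`,
#'   `combined`), `wilcoxon` (data.frame: `pair`, `statistic`, `p_value`,
#'   `degenerate`) and `skipped` (integer indices of rejected fixtures).
#' @export
benchmark_methods <- function(fixtures, cutoff = 0.85,
                              partitioner = c("pam2", "kmeans2"),
                              min_split = 2, seed = 1,
                              refine_threshold = 0.5,
                              max_cluster_size = 50) {
  partitioner <- match.arg(partitioner)
  if (length(fixtures) < 2) stop_input("benchmark needs at least 2 fixtures")
  rows <- list()
  skipped <- integer(0)
  for (i in seq_along(fixtures)) {
    S <- fixtures[[i]]
    ok <- tryCatch({ validate_similarity(S); TRUE },
                   gocondense_input_error = function(e) FALSE)
    if (!ok) {
      skipped <- c(skipped, i)
      message(sprintf("fixture %d failed the matrix contract; skipped", i))
      next
    }
    score_of <- function(a) {
      if (a$n_clusters < 2) NA_real_ else difference_score(S, a)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      fixture = i,
      binary = score_of(binary_cut(S, cutoff, partitioner, min_split, seed)),
      hclust = score_of(hierarchical_cluster(S)),
      combined = score_of(combined_cluster(S, cutoff, partitioner, min_split,
                                           seed, refine_threshold,
                                           max_cluster_size)))
  }
  scores <- do.call(rbind, rows)
  pairs <- list(c("binary", "hclust"), c("binary", "combined"),
                c("hclust", "combined"))
  wil <- do.call(rbind, lapply(pairs, function(p) {
    x <- scores[[p[1]]]
    y <- scores[[p[2]]]
    keep <- !is.na(x) & !is.na(y)
    d <- x[keep] - y[keep]
    if (all(d == 0)) {
      data.frame(pair = paste(p, collapse = " vs "), statistic = NA_real_,
                 p_value = 1, degenerate = TRUE)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x[keep], y[keep],
                                                paired = TRUE))
      data.frame(pair = paste(p, collapse = " vs "),
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 degenerate = FALSE)
    }
  }))
  list(scores = scores, wilcoxon = wil, skipped = skipped)
}

#' Export a cluster assignment as TSV
#'
#' @param assignment A `cluster_assignment`.
#' @param path Output path.
#' @export
write_clusters_tsv <- function(assignment, path) {
  df <- data.frame(term_id = names(assignment$labels),
                   cluster = unname(assignment$labels),
                   method = assignment$method, stringsAsFactors = FALSE)
  write_tsv_atomic(df, path)
}
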