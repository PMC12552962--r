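# Independent oracles used by the test suite. Each re-derives the quantity
# under test by a different route (breadth-first search, boolean matrix
# closure, exhaustive scans, double loops) and never calls the package code
# path it checks.

# Shortest-path levels via igraph: distance from the root over parent->child
# edges, plus one.
oracle_levels <- function(g) {
  alive <- names(g$parents)
  el <- do.call(rbind, lapply(alive, function(id) {
    if (length(g$parents[[id]]) == 0) return(NULL)
    cbind(g$parents[[id]], id)
  }))
  ig <- igraph::graph_from_edgelist(el, directed = TRUE)
  d <- igraph::distances(ig, v = g$root_id, mode = "out")[1, ]
  lv <- stats::setNames(rep(NA_integer_, length(alive)), alive)
  lv[names(d)] <- as.integer(d + 1)
  lv[g$root_id] <- 1L
  lv
}

# Transitive ancestor closure by boolean matrix powers over the
# child -> parent adjacency matrix.
oracle_closure <- function(g) {
  alive <- names(g$parents)
  n <- length(alive)
  A <- matrix(FALSE, n, n, dimnames = list(alive, alive))
  for (id in alive) A[id, g$parents[[id]]] <- TRUE
  R <- A
  repeat {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R  # R[u, v] TRUE iff v is a (proper) ancestor of u
}

# Exhaustive-MICA similarity: scan every common ancestor-or-self for the
# maximal IC and apply the measure formula directly.
oracle_similarity <- function(closure, ic, t1, t2, measure) {
  a1 <- c(t1, colnames(closure)[closure[t1, ]])
  a2 <- c(t2, colnames(closure)[closure[t2, ]])
  if (measure == "jaccard_anc") {
    return(length(intersect(a1, a2)) / length(union(a1, a2)))
  }
  mica <- -Inf
  for (a in intersect(a1, a2)) mica <- max(mica, ic[[a]])
  if (measure == "resnik_norm") {
    mx <- max(ic)
    return(if (mx == 0) 0 else mica / mx)
  }
  den <- ic[[t1]] + ic[[t2]]
  lin <- if (den == 0) 0 else 2 * mica / den
  if (measure == "lin") lin else lin * (1 - exp(-mica))
}

# Difference score by an independent double loop over all index pairs.
oracle_difference_score <- function(S, labels) {
  n <- nrow(S)
  w <- c(); b <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (labels[i] == labels[j]) w <- c(w, S[i, j]) else b <- c(b, S[i, j])
    }
  }
  (if (length(w) == 0) 0 else mean(w)) - mean(b)
}

# Independent greedy representative selection: every round re-enumerates ALL
# terms of the graph as candidates against the brute-force closure.
oracle_representatives <- function(g, members, min_cover, min_level,
                                   max_reps) {
  closure <- oracle_closure(g)
  anc_or_self <- function(t) c(t, colnames(closure)[closure[t, ]])
  uncovered <- members
  picks <- character(0)
  covered_sets <- list()
  while (length(uncovered) > 0 && length(picks) < max_reps) {
    best <- NULL
    for (a in names(g$parents)) {            # scan the whole graph
      if (g$levels[[a]] < min_level) next
      cov <- uncovered[vapply(uncovered, function(t) a %in% anc_or_self(t),
                              logical(1))]
      if (length(cov) < min_cover) next
      cand <- list(id = a, lev = g$levels[[a]], cov = cov)
      if (is.null(best) ||
          cand$lev > best$lev ||
          (cand$lev == best$lev && length(cand$cov) > length(best$cov)) ||
          (cand$lev == best$lev && length(cand$cov) == length(best$cov) &&
           cand$id < best$id)) {
        best <- cand
      }
    }
    if (is.null(best)) break
    picks <- c(picks, best$id)
    covered_sets[[length(covered_sets) + 1L]] <- best$cov
    uncovered <- setdiff(uncovered, best$cov)
  }
  for (t in uncovered) {
    picks <- c(picks, t)
    covered_sets[[length(covered_sets) + 1L]] <- t
  }
  list(term_id = picks, covered = covered_sets)
}

# Partition agreement (adjusted Rand index), chance-corrected.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# A small hand-built diamond ontology used across files:
# R <- a, R <- b, b <- c, {a, c} <- d
diamond_obo <- c(
  "[Term]", "id: X:R", "name: root", "",
  "[Term]", "id: X:a", "name: a", "is_a: X:R", "",
  "[Term]", "id: X:b", "name: b", "is_a: X:R", "",
  "[Term]", "id: X:c", "name: c", "is_a: X:b", "",
  "[Term]", "id: X:d", "name: d", "is_a: X:a", "is_a: X:c", "")

random_dag <- function(n, seed, depth = 5) {
  synth_dag(n, max_parents = 3, depth_target = depth, seed = seed)$graph
}
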