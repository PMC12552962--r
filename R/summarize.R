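#' Representative terms for one cluster
#'
#' Labels a cluster of ontology terms with the most specific common ancestors
#' that cover its members, replacing fragmented keyword summaries with whole
#' readable terms. The selection is a greedy cover:
#'
#' 1. Candidates are every ancestor-or-self of a still-uncovered member whose
#'    level is at least `min_level` and which covers at least `min_cover`
#'    uncovered members ("covers" = is the member itself or one of its
#'    ancestors).
#' 2. The candidate with the deepest level wins; ties go to the larger number
#'    of covered members, then to the lexicographically smallest term id.
#' 3. Its covered members are removed and the loop repeats until the cluster
#'    is covered, no candidate qualifies, or `max_reps` representatives have
#'    been selected.
#'
#' Members still uncovered at the end each become their own representative,
#' so the covering sets always partition the cluster. A representative may be
#' a pure ancestor that is not itself an input term; the output flags this.
#'
#' @param g An `ontology_graph`.
#' @param cluster_members Character vector of member term ids.
#' @param min_cover Minimum number of uncovered members a candidate must
#'   cover (default 2; prevents over-specific single-member picks).
#' @param min_level Minimum level of a candidate (default 3; excludes the
#'   root and its immediate children, which are too generic to label a
#'   cluster).
#' @param max_reps Display budget for greedy picks per cluster (default 5).
#' @return A `representative_set`: list with `members` and `representatives`,
#'   the latter a data.frame with columns `term_id`, `name`, `level`,
#'   `n_covered`, `covered` (list column), `is_member`, `self_rep` — rows in
#'   selection order.
#' @export
representative_terms <- function(g, cluster_members, min_cover = 2,
                                 min_level = 3, max_reps = 5) {
  if (length(cluster_members) < 1) {
    stop_input("cluster_members must be non-empty")
  }
  check_term(g, cluster_members)
  if (min_cover < 1) stop_input("min_cover must be >= 1")

  clo <- ancestor_closure(g, cluster_members)
  uncovered <- cluster_members
  picks <- list()
  while (length(uncovered) > 0 && length(picks) < max_reps) {
    cands <- unique(unlist(clo[uncovered], use.names = FALSE))
    cands <- cands[g$levels[cands] >= min_level]
    if (length(cands) == 0) break
    cover <- lapply(cands, function(a) {
      uncovered[vapply(clo[uncovered], function(cl) a %in% cl, logical(1))]
    })
    ncov <- lengths(cover)
    ok <- ncov >= min_cover
    if (!any(ok)) break
    cands <- cands[ok]
    cover <- cover[ok]
    ncov <- ncov[ok]
    lev <- unname(g$levels[cands])
    # priority: deepest level, then coverage, then smallest term id
    ord <- order(-lev, -ncov, cands)
    best <- ord[[1]]
    picks[[length(picks) + 1L]] <- list(term_id = cands[[best]],
                                        covered = cover[[best]])
    uncovered <- setdiff(uncovered, cover[[best]])
  }
  for (t in uncovered) {
    picks[[length(picks) + 1L]] <- list(term_id = t, covered = t)
  }

  rep_ids <- vapply(picks, function(p) p$term_id, character(1))
  covered <- lapply(picks, function(p) p$covered)
  reps <- data.frame(
    term_id = rep_ids,
    name = g$terms$name[match(rep_ids, g$terms$term_id)],
    level = unname(g$levels[rep_ids]),
    n_covered = lengths(covered),
    is_member = rep_ids %in% cluster_members,
    self_rep = vapply(seq_along(picks), function(i) {
      identical(covered[[i]], rep_ids[[i]])
    }, logical(1)),
    stringsAsFactors = FALSE
  )
  reps$covered <- I(covered)
  structure(list(members = cluster_members, representatives = reps),
            class = "representative_set")
}

#' @export
print.representative_set <- function(x, ...) {
  cat(sprintf("representative_set: %d members, %d representative(s)\n",
              length(x$members), nrow(x$representatives)))
  for (i in seq_len(nrow(x$representatives))) {
    r <- x$representatives[i, ]
    cat(sprintf("  %d. %s (%s, level %d) covers %d\n", i, r$term_id, r$name,
                r$level, r$n_covered))
  }
  invisible(x)
}

#' Representative terms for every cluster of an assignment
#'
#' @param g An `ontology_graph`.
#' @param assignment A `cluster_assignment` over terms of `g`.
#' @inheritParams representative_terms
#' @return Named list of `representative_set` objects, one per cluster index.
#' @export
summarize_clusters <- function(g, assignment, min_cover = 2, min_level = 3,
                               max_reps = 5) {
  out <- lapply(seq_len(assignment$n_clusters), function(k) {
    representative_terms(g, names(assignment$labels)[assignment$labels == k],
                         min_cover = min_cover, min_level = min_level,
                         max_reps = max_reps)
  })
  stats::setNames(out, as.character(seq_len(assignment$n_clusters)))
}

#' Broad-term panel
#'
#' For a biological overview above the heatmap: every ontology term at
#' `broad_level` (default 2, the direct children of the root — e.g. "immune
#' system process", "metabolic process" in GO) is labeled with the percentage
#' of input terms that are the broad term itself or one of its descendants.
#' In a DAG a term may descend from several broad terms and then counts
#' toward each, so percentages need not sum to 100.
#'
#' @param g An `ontology_graph`.
#' @param input_terms Character vector of input term ids.
#' @param broad_level Level of the panel terms (>= 2).
#' @param top_k Number of panel entries to keep (by descending percentage;
#'   ties broken by term id). Zero-percentage entries are dropped.
#' @return A data.frame of class `broad_panel` with columns `term_id`,
#'   `name`, `percentage`.
#' @export
broad_term_panel <- function(g, input_terms, broad_level = 2, top_k = 8) {
  check_term(g, input_terms)
  if (broad_level < 2) stop_input("broad_level must be >= 2")
  broad <- names(g$levels)[g$levels == broad_level]
  if (length(broad) == 0) {
    stop_structure("no term at level %d in the ontology", broad_level)
  }
  clo <- ancestor_closure(g, input_terms)
  pct <- vapply(broad, function(b) {
    100 * sum(vapply(clo, function(cl) b %in% cl, logical(1))) /
      length(input_terms)
  }, numeric(1))
  keep <- pct > 0
  broad <- broad[keep]
  pct <- pct[keep]
  ord <- order(-pct, broad)
  take <- utils::head(ord, top_k)
  out <- data.frame(term_id = broad[take],
                    name = g$terms$name[match(broad[take], g$terms$term_id)],
                    percentage = unname(pct[take]), stringsAsFactors = FALSE)
  class(out) <- c("broad_panel", "data.frame")
  out
}

#' Rank clusters by mean score
#'
#' Orders clusters by the magnitude of their mean enrichment score —
#' descending `|mean|`, so for a negative-NES analysis the most strongly
#' down-regulated cluster still comes first. Ties go to the larger cluster,
#' then to the smaller cluster index. The heatmap display order follows this
#' ranking.
#'
#' @param table An `enrichment_table` scoring every clustered term.
#' @param assignment A `cluster_assignment`.
#' @return Data.frame with columns `rank`, `cluster`, `mean_score`, `size`,
#'   one row per cluster in display order.
#' @export
rank_clusters <- function(table, assignment) {
  missing <- setdiff(names(assignment$labels), table$term_id)
  if (length(missing) > 0) {
    stop_input("clustered term(s) missing from the enrichment table: %s",
               paste(missing, collapse = ", "))
  }
  sc <- stats::setNames(table$score, table$term_id)
  ks <- seq_len(assignment$n_clusters)
  mean_score <- vapply(ks, function(k) {
    mean(sc[names(assignment$labels)[assignment$labels == k]])
  }, numeric(1))
  size <- as.integer(tabulate(assignment$labels, assignment$n_clusters))
  ord <- order(-abs(mean_score), -size, ks)
  data.frame(rank = seq_along(ks), cluster = ks[ord],
             mean_score = mean_score[ord], size = size[ord])
}

#' Export representatives of all clusters as TSV
#'
#' Columns: `cluster`, `rank`, `term_id`, `name`, `level`, `n_covered`,
#' `covered_ids` (comma-joined), `is_member`.
#'
#' @param reps Named list of `representative_set` (see
#'   [summarize_clusters()]).
#' @param path Output path.
#' @export
write_representatives_tsv <- function(reps, path) {
  rows <- lapply(names(reps), function(k) {
    r <- reps[[k]]$representatives
    data.frame(cluster = as.integer(k), rank = seq_len(nrow(r)),
               term_id = r$term_id, name = r$name, level = r$level,
               n_covered = r$n_covered,
               covered_ids = vapply(r$covered, paste, character(1),
                                    collapse = ","),
               is_member = r$is_member, stringsAsFactors = FALSE)
  })
  write_tsv_atomic(do.call(rbind, rows), path)
}

#' Export a broad-term panel as TSV
#'
#' @param panel A `broad_panel`.
#' @param path Output path.
#' @export
write_panel_tsv <- function(panel, path) {
  write_tsv_atomic(as.data.frame(panel), path)
}
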