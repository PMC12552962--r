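# Synthetic-fixture generators: every module of the package is testable
# without downloading GO or MSigDB. Seeds are mandatory; no generator
# touches the global RNG stream.

#' Generate a random rooted ontology DAG
#'
#' Terms are created in level order: the root first, then terms spread over
#' levels `2 .. depth_target`. Every non-root term receives one parent drawn
#' uniformly from the level directly above it plus 0 to `max_parents - 1`
#' extra parents drawn uniformly from any shallower term, so diamonds and
#' shortest/longest path divergence arise naturally. Edge relations are
#' sampled as `is_a` (80%) or `part_of` (20%). The generator emits both the
#' in-memory graph and a round-trippable OBO document, and is deterministic
#' per seed.
#'
#' @param n_terms Number of terms (>= 2).
#' @param max_parents Maximum parents per term (>= 1).
#' @param depth_target Deepest assigned level (>= 2); the realized depth may
#'   be smaller because extra parents can shorten a term's path to the root.
#' @param seed Integer seed (mandatory).
#' @return List with `graph` (an `ontology_graph`, produced by parsing the
#'   emitted document — the round trip is built in) and `obo` (character
#'   vector of OBO lines).
#' @export
synth_dag <- function(n_terms, max_parents = 3, depth_target = 4, seed) {
  if (n_terms < 2) stop_input("n_terms must be >= 2")
  if (max_parents < 1) stop_input("max_parents must be >= 1")
  if (depth_target < 2) stop_input("depth_target must be >= 2")
  ids <- sprintf("SYN:%07d", seq_len(n_terms))
  obo <- with_seed(seed, {
    # assigned levels: one term per level 2..depth_target first (so every
    # level is inhabited when n allows), the rest uniform
    lv <- integer(n_terms)
    lv[1] <- 1L
    rest <- seq_len(n_terms)[-1]
    fill <- seq(2, depth_target)
    fill <- fill[seq_len(min(length(fill), length(rest)))]
    lv[rest[seq_along(fill)]] <- fill
    if (length(rest) > length(fill)) {
      lv[rest[-seq_along(fill)]] <-
        sample(seq(2, depth_target), length(rest) - length(fill),
               replace = TRUE)
    }
    lv <- sort(lv)
    lines <- c("format-version: 1.2", "")
    for (i in seq_len(n_terms)) {
      lines <- c(lines, "[Term]", paste0("id: ", ids[i]),
                 paste0("name: synthetic term ", i),
                 "namespace: synthetic")
      if (i > 1) {
        above <- which(lv == lv[i] - 1L)
        primary <- if (length(above) == 1) above else sample(above, 1)
        shallower <- setdiff(which(lv < lv[i]), primary)
        n_extra <- sample.int(max_parents, 1) - 1L
        extra <- if (n_extra > 0 && length(shallower) > 0) {
          if (length(shallower) == 1) shallower[seq_len(min(1, n_extra))]
          else sample(shallower, min(n_extra, length(shallower)))
        } else integer(0)
        for (p in c(primary, extra)) {
          rel <- sample(c("is_a", "part_of"), 1, prob = c(0.8, 0.2))
          lines <- c(lines, if (rel == "is_a") paste0("is_a: ", ids[p])
                     else paste0("relationship: part_of ", ids[p]))
        }
      }
      lines <- c(lines, "")
    }
    lines
  })
  list(graph = parse_obo(obo), obo = obo)
}

#' Generate a planted-block similarity matrix
#'
#' Within-block entries are drawn uniformly from `within_range`, cross-block
#' entries from `between_range`; the matrix is symmetric by construction with
#' unit diagonal. `within_range[1] > between_range[2]` is enforced so that
#' planted-recovery tests are well-posed. The planted labels are returned for
#' adjusted-Rand-index scoring.
#'
#' @param block_sizes Integer vector of block sizes (all >= 1).
#' @param within_range,between_range Length-2 ranges inside `[0, 1]`.
#' @param seed Integer seed (mandatory).
#' @return List with `S` (similarity matrix, term ids `T001`, ...) and
#'   `labels` (named integer vector of planted block memberships).
#' @export
synth_similarity <- function(block_sizes, within_range = c(0.75, 0.95),
                             between_range = c(0, 0.15), seed) {
  if (length(block_sizes) == 0 || any(block_sizes < 1)) {
    stop_input("block_sizes must be a non-empty vector of positive integers")
  }
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2] && r[1] >= 0 && r[2] <= 1
  if (!rng_ok(within_range) || !rng_ok(between_range)) {
    stop_input("ranges must be (lo, hi) inside [0, 1]")
  }
  if (within_range[1] <= between_range[2]) {
    stop_input("within_range.lo must exceed between_range.hi (separation)")
  }
  n <- sum(block_sizes)
  labels <- rep(seq_along(block_sizes), block_sizes)
  ids <- sprintf("T%03d", seq_len(n))
  S <- with_seed(seed, {
    M <- diag(1, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        r <- if (labels[i] == labels[j]) within_range else between_range
        v <- stats::runif(1, r[1], r[2])
        M[i, j] <- v
        M[j, i] <- v
      }
    }
    M
  })
  dimnames(S) <- list(ids, ids)
  class(S) <- c("similarity_matrix", class(S))
  list(S = S, labels = stats::setNames(labels, ids))
}

#' Generate a synthetic enrichment table
#'
#' Samples `n_terms` terms without replacement from the ontology and attaches
#' scores: NES drawn uniformly from `[1.2, 3]` times `nes_sign`, or overlap
#' proportions drawn uniformly from `(0, 1]`.
#'
#' @param g An `ontology_graph`.
#' @param n_terms Number of terms to sample (`<= |g|`).
#' @param score_type `"nes"` or `"overlap"`.
#' @param seed Integer seed (mandatory).
#' @param nes_sign `+1` or `-1`, the sign of all NES scores.
#' @return An `enrichment_table`.
#' @export
synth_enrichment <- function(g, n_terms, score_type = c("nes", "overlap"),
                             seed, nes_sign = 1) {
  score_type <- match.arg(score_type)
  alive <- names(g$parents)
  if (n_terms > length(alive)) {
    stop_input("n_terms (%d) exceeds ontology size (%d)", n_terms,
               length(alive))
  }
  if (!nes_sign %in% c(-1, 1)) stop_input("nes_sign must be +1 or -1")
  with_seed(seed, {
    ids <- if (n_terms == length(alive)) alive else sample(alive, n_terms)
    score <- if (score_type == "nes") {
      nes_sign * stats::runif(n_terms, 1.2, 3)
    } else {
      stats::runif(n_terms, 0.01, 1)
    }
    enrichment_table(ids, score, score_type,
                     padj = stats::runif(n_terms, 0, 0.05))
  })
}

#' Generate a synthetic term-to-gene annotation map
#'
#' Assigns each leaf-ward term a handful of genes from a shared pool; useful
#' for exercising annotation-based information content.
#'
#' @param g An `ontology_graph`.
#' @param n_genes Size of the gene pool.
#' @param genes_per_term Range (lo, hi) of direct annotations per term.
#' @param seed Integer seed (mandatory).
#' @return Named list mapping term ids to gene symbol vectors.
#' @export
synth_annotations <- function(g, n_genes = 200, genes_per_term = c(1, 5),
                              seed) {
  pool <- sprintf("gene%04d", seq_len(n_genes))
  alive <- names(g$parents)
  with_seed(seed, {
    stats::setNames(lapply(alive, function(t) {
      k <- sample(seq(genes_per_term[1], genes_per_term[2]), 1)
      sample(pool, min(k, n_genes))
    }), alive)
  })
}

#' Write a complete synthetic input bundle to a directory
#'
#' Emits `ontology.obo`, `enrichment.tsv`, and `annotations.gmt` so the full
#' pipeline can be run end to end from files. Backs the `simulate` CLI
#' subcommand.
#'
#' @param dir Output directory (created if missing).
#' @param n_terms Ontology size.
#' @param n_enriched Number of enriched terms to sample.
#' @param score_type `"nes"` or `"overlap"`.
#' @param seed Integer seed.
#' @param depth_target,max_parents Passed to [synth_dag()].
#' @return Invisibly, a named list of the written paths.
#' @export
simulate_fixtures <- function(dir, n_terms = 300, n_enriched = 100,
                              score_type = "nes", seed = 1,
                              depth_target = 6, max_parents = 3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dag <- synth_dag(n_terms, max_parents = max_parents,
                   depth_target = depth_target, seed = seed)
  tab <- synth_enrichment(dag$graph, n_enriched, score_type, seed = seed + 1)
  ann <- synth_annotations(dag$graph, seed = seed + 2)
  paths <- list(obo = file.path(dir, "ontology.obo"),
                enrichment = file.path(dir, "enrichment.tsv"),
                gmt = file.path(dir, "annotations.gmt"))
  write_atomic(paths$obo, function(tmp) writeLines(dag$obo, tmp))
  write_tsv_atomic(as.data.frame(tab)[, c("term_id", "score", "padj")],
                   paths$enrichment)
  write_gmt(structure(list(sets = ann, source_label = "synthetic"),
                      class = "gene_set_collection"), paths$gmt)
  invisible(paths)
}
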