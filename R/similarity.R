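#' Information content of ontology terms
#'
#' Information content (IC, in nats) drives the IC-based semantic similarity
#' measures. Two sources are supported:
#'
#' * **Annotation-based** (when `annotations` is supplied): the annotation
#'   probability of a term is the number of genes annotated to the term or to
#'   any of its descendants, divided by the number of genes annotated anywhere
#'   in the ontology; `ic = -ln p`. A term of the graph with zero propagated
#'   count receives a pseudo-count of 1 (with a warning) so its IC is finite.
#' * **Structural fallback** (default): `ic(t) = -ln((d(t) + 1) / N)` where
#'   `d(t)` is the number of descendants of `t` and `N` the number of
#'   non-obsolete terms. The root then has IC 0 and leaves the maximal IC.
#'
#' Either way IC is 0 at the root and non-decreasing along root-to-leaf paths.
#'
#' @param g An `ontology_graph`.
#' @param annotations Optional named list mapping term ids to character
#'   vectors of gene symbols (direct annotations; propagation to ancestors is
#'   performed internally).
#' @return Named numeric vector of class `information_content` (nats), one
#'   entry per non-obsolete term.
#' @export
information_content <- function(g, annotations = NULL) {
  alive <- names(g$parents)
  n <- length(alive)
  if (is.null(annotations)) {
    d <- vapply(alive, function(t) length(descendants(g, t)), integer(1))
    ic <- -log((d + 1) / n)
  } else {
    check_term(g, names(annotations))
    corpus <- unique(unlist(annotations, use.names = FALSE))
    total <- length(corpus)
    if (total == 0) stop_input("annotation map contains no genes")
    counts <- vapply(alive, function(t) {
      fam <- c(t, descendants(g, t))
      length(unique(unlist(annotations[intersect(fam, names(annotations))],
                           use.names = FALSE)))
    }, integer(1))
    if (any(counts == 0)) {
      warning(sprintf(
        "%d term(s) with zero propagated annotations assigned pseudo-count 1",
        sum(counts == 0)))
      counts[counts == 0] <- 1L
    }
    ic <- -log(counts / total)
  }
  ic <- pmax(ic, 0)
  structure(stats::setNames(ic, alive), class = "information_content")
}

#' Semantic similarity between two terms
#'
#' All measures are symmetric and bounded in `[0, 1]`. The IC-based measures
#' pivot on the most informative common ancestor (MICA): the shared
#' ancestor-or-self with maximal information content.
#'
#' * `rel` — Schlicker relevance: `lin * (1 - exp(-ic(MICA)))`. Downweights
#'   pairs whose MICA is uninformative (near the root).
#' * `lin` — `2 * ic(MICA) / (ic(t1) + ic(t2))`, 0 if the denominator is 0.
#' * `resnik_norm` — `ic(MICA)` normalized by the maximal IC in the graph.
#' * `jaccard_anc` — Jaccard index of the two ancestor-or-self closures; needs
#'   no IC.
#'
#' @param g An `ontology_graph`.
#' @param t1,t2 Term ids in `g`.
#' @param measure One of `"rel"`, `"lin"`, `"resnik_norm"`, `"jaccard_anc"`.
#' @param ic An `information_content` vector (required unless
#'   `measure = "jaccard_anc"`); defaults to the structural IC of `g`.
#' @return A similarity in `[0, 1]`.
#' @export
term_similarity <- function(g, t1, t2,
                            measure = c("rel", "lin", "resnik_norm",
                                        "jaccard_anc"),
                            ic = NULL) {
  measure <- match.arg(measure)
  check_term(g, c(t1, t2))
  if (measure != "jaccard_anc" && is.null(ic)) ic <- information_content(g)
  a1 <- c(t1, ancestors(g, t1))
  a2 <- c(t2, ancestors(g, t2))
  pair_similarity(a1, a2, measure, ic,
                  ic_max = if (is.null(ic)) NULL else max(ic))
}

# Core pairwise kernel over precomputed ancestor-or-self closures.
pair_similarity <- function(a1, a2, measure, ic, ic_max = NULL) {
  if (measure == "jaccard_anc") {
    return(length(intersect(a1, a2)) / length(union(a1, a2)))
  }
  ca <- intersect(a1, a2)
  mica <- max(ic[ca])
  t1 <- a1[[1]]
  t2 <- a2[[1]]
  val <- switch(measure,
    lin = {
      den <- ic[[t1]] + ic[[t2]]
      if (den == 0) 0 else 2 * mica / den
    },
    rel = {
      den <- ic[[t1]] + ic[[t2]]
      lin <- if (den == 0) 0 else 2 * mica / den
      lin * (1 - exp(-mica))
    },
    resnik_norm = {
      if (is.null(ic_max)) ic_max <- max(ic)
      if (ic_max == 0) 0 else mica / ic_max
    }
  )
  min(max(val, 0), 1)
}

#' Pairwise similarity matrix over the enriched terms
#'
#' Builds the symmetric term-by-term similarity matrix that the clustering
#' operates on. Terms of the enrichment table absent from the ontology are
#' dropped with a warning; at least two terms must remain.
#'
#' @param g An `ontology_graph`.
#' @param table An `enrichment_table` (or character vector of term ids).
#' @param measure Similarity measure, see [term_similarity()]. Default `rel`.
#' @param ic Optional `information_content`; computed structurally if needed.
#' @return A symmetric numeric matrix with unit diagonal, dimnames set to the
#'   retained term ids, class `c("similarity_matrix", "matrix")`.
#' @export
similarity_matrix <- function(g, table,
                              measure = c("rel", "lin", "resnik_norm",
                                          "jaccard_anc"),
                              ic = NULL) {
  measure <- match.arg(measure)
  ids <- if (is.character(table)) table else table$term_id
  if (anyDuplicated(ids)) {
    stop_input("duplicated term id(s) in input: %s",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  known <- ids %in% names(g$parents)
  if (any(!known)) {
    warning(sprintf("dropping %d term(s) absent from the ontology: %s",
                    sum(!known),
                    paste(utils::head(ids[!known], 5), collapse = ", ")))
  }
  ids <- ids[known]
  if (length(ids) < 2) {
    stop_input("fewer than 2 terms retained; clustering is undefined")
  }
  if (measure != "jaccard_anc" && is.null(ic)) ic <- information_content(g)
  ic_max <- if (is.null(ic)) NULL else max(ic)
  clo <- ancestor_closure(g, ids)
  n <- length(ids)
  S <- diag(1, n)
  dimnames(S) <- list(ids, ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- pair_similarity(clo[[i]], clo[[j]], measure, ic, ic_max)
      S[i, j] <- v
      S[j, i] <- v
    }
  }
  class(S) <- c("similarity_matrix", class(S))
  S
}

# Contract check shared by the clustering entry points.
validate_similarity <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    stop_input("similarity matrix must be square")
  }
  if (is.null(rownames(S))) {
    dimnames(S) <- list(paste0("item", seq_len(nrow(S))),
                        paste0("item", seq_len(nrow(S))))
  }
  if (anyDuplicated(rownames(S))) {
    stop_input("similarity matrix has duplicated term ids")
  }
  if (max(abs(S - t(S))) > 1e-8) {
    stop_input("similarity matrix is not symmetric")
  }
  if (min(S) < -1e-12 || max(S) > 1 + 1e-12) {
    stop_input("similarity values must lie in [0, 1]")
  }
  if (max(abs(diag(S) - 1)) > 1e-12) {
    stop_input("similarity matrix diagonal must be 1")
  }
  invisible(TRUE)
}

#' Export a similarity matrix as TSV
#'
#' @param S A similarity matrix with dimnames.
#' @param path Output path.
#' @export
write_similarity_tsv <- function(S, path) {
  df <- data.frame(term_id = rownames(S), as.data.frame(unclass(S)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_atomic(df, path)
}

#' Read a term-to-gene annotation map
#'
#' Accepts a GMT file (one term per line) or a two-column TSV
#' (`term_id<TAB>gene`, one pair per line, no header requirement beyond an
#' optional `term_id` header line).
#'
#' @param path Input path.
#' @return Named list mapping term ids to character vectors of genes.
#' @export
read_annotations <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  nf <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (nf >= 3) {
    gs <- read_gmt(path)
    return(gs$sets)
  }
  df <- utils::read.delim(path, header = grepl("term_id", first),
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("term_id", "gene")
  split(df$gene, df$term_id)
}
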