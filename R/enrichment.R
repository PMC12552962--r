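#' Build a validated enrichment table
#'
#' The quantitative input of the pipeline: the significant ontology terms
#' together with one score per term. Two score semantics are supported:
#'
#' * `"nes"` — the normalized enrichment score of GSEA. NES is signed
#'   (direction of regulation), so a single analysis must contain terms of a
#'   single sign: up- and down-regulated terms are condensed in separate
#'   runs. A mixed-sign table is rejected.
#' * `"overlap"` — the over-representation-analysis proportion of overlapping
#'   genes relative to the total number of genes in the term; all scores must
#'   lie in `[0, 1]`.
#'
#' @param term_id Character vector of unique term ids.
#' @param score Numeric scores, one per term.
#' @param score_type `"nes"` or `"overlap"`.
#' @param padj Optional adjusted p-values in `[0, 1]`.
#' @param genes Optional list of character vectors (leading-edge or overlap
#'   genes per term).
#' @return A data.frame of class `enrichment_table` with attribute
#'   `score_type`.
#' @export
enrichment_table <- function(term_id, score, score_type = c("nes", "overlap"),
                             padj = NULL, genes = NULL) {
  score_type <- match.arg(score_type)
  term_id <- as.character(term_id)
  score <- as.numeric(score)
  if (length(term_id) != length(score)) {
    stop_input("term_id and score lengths differ (%d vs %d)",
               length(term_id), length(score))
  }
  if (anyDuplicated(term_id)) {
    stop_input("duplicated term id(s) in enrichment table: %s",
               paste(unique(term_id[duplicated(term_id)]), collapse = ", "))
  }
  if (anyNA(score)) stop_input("enrichment scores must not be NA")
  if (score_type == "overlap") {
    if (any(score < 0 | score > 1)) {
      stop_input("overlap-proportion scores must lie in [0, 1]")
    }
  } else {
    sg <- unique(sign(score[score != 0]))
    if (length(sg) > 1) {
      stop_input(paste(
        "mixed-sign NES scores: a single analysis must use terms with",
        "either positive or negative NES; split the table by sign and",
        "condense each direction separately"))
    }
  }
  tab <- data.frame(term_id = term_id, score = score,
                    stringsAsFactors = FALSE)
  if (!is.null(padj)) {
    padj <- as.numeric(padj)
    if (length(padj) != length(term_id) ||
        any(!is.na(padj) & (padj < 0 | padj > 1))) {
      stop_input("padj must match term_id length with values in [0, 1]")
    }
    tab$padj <- padj
  }
  if (!is.null(genes)) {
    if (length(genes) != length(term_id)) {
      stop_input("genes list must match term_id length")
    }
    tab$genes <- I(lapply(genes, as.character))
  }
  attr(tab, "score_type") <- score_type
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

#' Read an enrichment table from TSV
#'
#' Expects header columns `term_id` and `score`; optional `padj` and `genes`
#' (comma-separated gene symbols).
#'
#' @param path TSV file path.
#' @param score_type `"nes"` or `"overlap"`.
#' @return An `enrichment_table`.
#' @export
read_enrichment_tsv <- function(path, score_type = c("nes", "overlap")) {
  score_type <- match.arg(score_type)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term_id", "score") %in% names(df))) {
    stop_input("enrichment TSV '%s' must have columns term_id and score", path)
  }
  genes <- if ("genes" %in% names(df)) {
    lapply(strsplit(df$genes, ","), function(x) trimws(x[x != ""]))
  } else NULL
  enrichment_table(df$term_id, df$score, score_type,
                   padj = if ("padj" %in% names(df)) df$padj else NULL,
                   genes = genes)
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("enrichment_table: %d terms, score_type = %s\n",
              nrow(x), attr(x, "score_type")))
  NextMethod()
}
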