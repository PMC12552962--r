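#' Read a GMT gene-set collection
#'
#' MSigDB dialect: one set per line, tab-separated `name`, `description`,
#' then gene symbols. Duplicate genes within a line are collapsed; empty
#' tokens (stray tabs) are dropped; gene case is preserved unless
#' `fold_case = TRUE`.
#'
#' @param gmt Path to a GMT file or a character vector of GMT lines.
#' @param source_label Free-text label for the collection.
#' @param fold_case Lower-case all gene symbols before storing.
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `source_label`.
#' @export
read_gmt <- function(gmt, source_label = "", fold_case = FALSE) {
  lines <- if (length(gmt) == 1 && !grepl("\n", gmt) && file.exists(gmt)) {
    readLines(gmt, warn = FALSE)
  } else if (length(gmt) == 1 && grepl("\n", gmt)) {
    strsplit(gmt, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(gmt)
  }
  lines <- lines[trimws(lines) != ""]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop_input("GMT line %d has %d field(s); need name, description, genes",
                 i, length(f))
    }
    name <- f[[1]]
    if (name %in% names(sets)) {
      stop_input("duplicate gene-set name '%s' at GMT line %d", name, i)
    }
    genes <- f[-(1:2)]
    genes <- genes[genes != ""]
    if (fold_case) genes <- tolower(genes)
    genes <- unique(genes)
    if (length(genes) == 0) {
      stop_input("gene set '%s' (GMT line %d) has no genes", name, i)
    }
    sets[[name]] <- genes
  }
  structure(list(sets = sets, source_label = source_label),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection '%s': %d sets, %d distinct genes\n",
              x$source_label, length(x$sets),
              length(unique(unlist(x$sets, use.names = FALSE)))))
  invisible(x)
}

#' Write a gene-set collection as GMT
#'
#' @param gs A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(gs, path) {
  write_atomic(path, function(tmp) {
    writeLines(vapply(names(gs$sets), function(nm) {
      paste(c(nm, gs$source_label, gs$sets[[nm]]), collapse = "\t")
    }, character(1)), tmp)
  })
}

#' Cross-collection gene-overlap matrix
#'
#' `values[i, j] = |A_i intersect B_j| / |A_i|`: the proportion of each row
#' set's genes found in each column set, i.e. relative to the total number of
#' genes in the row set. The matrix is not symmetric in general; the
#' row-relative orientation is recorded in the `orientation` attribute.
#'
#' @param a,b `gene_set_collection` objects (rows come from `a`).
#' @return Numeric matrix of proportions in `[0, 1]` with class
#'   `overlap_matrix` and attribute `orientation = "row"`.
#' @export
overlap_matrix <- function(a, b) {
  if (length(a$sets) == 0 || length(b$sets) == 0) {
    stop_input("both collections must be non-empty")
  }
  m <- vapply(b$sets, function(bs) {
    vapply(a$sets, function(as) length(intersect(as, bs)) / length(as),
           numeric(1))
  }, numeric(length(a$sets)))
  m <- matrix(m, nrow = length(a$sets),
              dimnames = list(names(a$sets), names(b$sets)))
  structure(m, orientation = "row",
            class = c("overlap_matrix", class(m)))
}

#' Inclusion calls from an overlap matrix
#'
#' A row set is called *included* when its best column overlap reaches the
#' threshold (`>=`, so a row hitting the threshold exactly is included). The
#' argmax column is reported, ties resolved to the lexicographically smallest
#' column name.
#'
#' @param m An `overlap_matrix`.
#' @param threshold Inclusion threshold in `(0, 1]`. Default 0.8.
#' @return Data.frame with columns `set`, `best_match`, `proportion` (one
#'   row per included row set; zero rows if none qualify).
#' @export
inclusion_calls <- function(m, threshold = 0.8) {
  if (threshold <= 0 || threshold > 1) {
    stop_input("threshold must lie in (0, 1]")
  }
  rows <- lapply(rownames(m), function(rn) {
    v <- m[rn, ]
    best <- max(v)
    if (best < threshold) return(NULL)
    cols <- sort(colnames(m)[v == best])
    data.frame(set = rn, best_match = cols[[1]], proportion = best,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(set = character(0), best_match = character(0),
                      proportion = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Export an overlap matrix as TSV
#'
#' The first header field records the orientation of the proportions.
#'
#' @param m An `overlap_matrix`.
#' @param path Output path.
#' @export
write_overlap_tsv <- function(m, path) {
  df <- data.frame(set = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- sprintf("set[orientation=%s]", attr(m, "orientation"))
  write_tsv_atomic(df, path)
}
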