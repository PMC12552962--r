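#' Parse an OBO document into a rooted ontology DAG
#'
#' Reads the flat-file OBO dialect used by `go-basic.obo` (`[Term]` stanzas
#' with `id:`, `name:`, `namespace:`, `is_a:`, `relationship: part_of` and
#' `is_obsolete:` tags) and returns a rooted directed acyclic graph of terms.
#' Both `is_a` and `part_of` edges contribute to ancestry and to term levels;
#' other relationship types (`regulates`, `occurs_in`, ...) are ignored, which
#' matches the transitive backbone of the basic GO release.
#'
#' Term levels follow the common GO convention: the root has level 1 and every
#' other term has level `1 + min(level of its parents)`, i.e. one plus the
#' shortest path to the root. Broad terms therefore have small levels and
#' specific terms large levels.
#'
#' Obsolete terms are retained in the term table (flagged) but carry no edges
#' and no level. Edges that point at unknown or obsolete terms — typical for a
#' namespace-filtered parse of the full GO, where `part_of` may cross
#' namespaces — are dropped with a warning rather than an error.
#'
#' @param obo Either a path to an OBO file or a character vector of OBO lines.
#' @param namespace_filter Optional namespace (e.g. `"biological_process"`);
#'   only terms of that namespace are kept. The filtered graph must have
#'   exactly one root.
#' @return An object of class `ontology_graph`: a list with elements
#'   `terms` (data.frame: `term_id`, `name`, `namespace`, `is_obsolete`),
#'   `parents` / `children` (named lists of character vectors), `relations`
#'   (named list giving each child's edge relations, parallel to `parents`),
#'   `root_id`, and `levels` (named integer vector).
#' @examples
#' obo <- c("[Term]", "id: T:1", "name: root",
#'          "[Term]", "id: T:2", "name: child", "is_a: T:1 ! root")
#' g <- parse_obo(obo)
#' g$levels
#' @export
parse_obo <- function(obo, namespace_filter = NULL) {
  lines <- if (length(obo) == 1 && !grepl("\n", obo) && file.exists(obo)) {
    readLines(obo, warn = FALSE)
  } else if (length(obo) == 1 && grepl("\n", obo)) {
    strsplit(obo, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(obo)
  }

  stanzas <- parse_obo_stanzas(lines)
  if (length(stanzas) == 0) {
    stop_input("OBO document contains no [Term] stanza")
  }

  recs <- lapply(stanzas, identity)
  ids <- vapply(recs, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    stop_input("duplicate term id(s) in OBO input: %s",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(recs) <- ids

  if (!is.null(namespace_filter)) {
    keep <- vapply(recs, function(r) identical(r$namespace, namespace_filter),
                   logical(1))
    recs <- recs[keep]
    if (length(recs) == 0) {
      stop_input("no terms left after namespace filter '%s'", namespace_filter)
    }
  }
  ids <- names(recs)

  terms <- data.frame(
    term_id     = ids,
    name        = vapply(recs, function(r) r$name %||% r$id, character(1)),
    namespace   = vapply(recs, function(r) r$namespace %||% NA_character_,
                         character(1)),
    is_obsolete = vapply(recs, function(r) isTRUE(r$obsolete), logical(1)),
    row.names   = NULL, stringsAsFactors = FALSE
  )

  alive <- ids[!terms$is_obsolete]
  parents   <- stats::setNames(vector("list", length(alive)), alive)
  relations <- stats::setNames(vector("list", length(alive)), alive)
  n_dropped <- 0L
  for (id in alive) {
    p <- recs[[id]]$parents
    r <- recs[[id]]$rels
    ok <- p %in% alive
    if (any(!ok)) n_dropped <- n_dropped + sum(!ok)
    dup <- duplicated(p[ok])
    parents[[id]]   <- p[ok][!dup]
    relations[[id]] <- r[ok][!dup]
  }
  if (n_dropped > 0) {
    warning(sprintf(
      "dropped %d edge(s) pointing at obsolete, filtered or unknown terms",
      n_dropped))
  }

  roots <- alive[vapply(parents[alive], length, integer(1)) == 0]
  if (length(roots) != 1) {
    stop_structure(
      "ontology must have exactly one root after filtering; found %d: %s",
      length(roots), paste(roots, collapse = ", "))
  }

  children <- stats::setNames(vector("list", length(alive)), alive)
  for (id in alive) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }

  g <- structure(list(
    terms = terms, parents = parents, children = children,
    relations = relations, root_id = roots, levels = NULL,
    cache = new.env(parent = emptyenv())
  ), class = "ontology_graph")

  assert_acyclic(g)
  g$levels <- compute_levels(g)
  g
}

# Split OBO lines into [Term] stanza records with line-number-aware errors.
parse_obo_stanzas <- function(lines) {
  stanzas <- list()
  cur <- NULL
  cur_line <- NA_integer_
  flush <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$id)) {
      stop_input("malformed [Term] stanza starting at line %d: missing id",
                 cur_line)
    }
    stanzas[[length(stanzas) + 1L]] <<- cur
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (startsWith(ln, "[")) {
      flush()
      if (ln == "[Term]") {
        cur <- list(id = NULL, name = NULL, namespace = NULL,
                    obsolete = FALSE, parents = character(0),
                    rels = character(0))
        cur_line <- i
      }
      next
    }
    if (is.null(cur)) next  # header or non-Term stanza body
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 0) {
      stop_input("malformed OBO line %d: '%s'", i, lines[[i]])
    }
    key <- m[2]
    val <- sub("\\s*!.*$", "", m[3])  # strip trailing comment
    if (key == "id") {
      if (val == "") stop_input("empty id at line %d", i)
      cur$id <- val
    } else if (key == "name") {
      cur$name <- val
    } else if (key == "namespace") {
      cur$namespace <- val
    } else if (key == "is_obsolete") {
      cur$obsolete <- identical(trimws(val), "true")
    } else if (key == "is_a") {
      tgt <- trimws(val)
      if (tgt == "") stop_input("empty is_a target at line %d", i)
      cur$parents <- c(cur$parents, tgt)
      cur$rels <- c(cur$rels, "is_a")
    } else if (key == "relationship") {
      parts <- strsplit(trimws(val), "\\s+")[[1]]
      if (length(parts) < 2) {
        stop_input("malformed relationship at line %d: '%s'", i, lines[[i]])
      }
      if (parts[1] == "part_of") {
        cur$parents <- c(cur$parents, parts[2])
        cur$rels <- c(cur$rels, "part_of")
      }
    }
    # other keys (def:, synonym:, xref:, ...) are ignored
  }
  flush()
  stanzas
}

assert_acyclic <- function(g) {
  el <- edge_list(g)
  if (nrow(el) == 0) return(invisible(TRUE))
  ig <- igraph::graph_from_data_frame(el, directed = TRUE)
  if (!igraph::is_dag(ig)) {
    stop_structure("ontology edge relation contains a cycle")
  }
  invisible(TRUE)
}

edge_list <- function(g) {
  kids <- names(g$parents)
  n <- vapply(g$parents, length, integer(1))
  data.frame(child = rep(kids, n),
             parent = unlist(g$parents, use.names = FALSE),
             stringsAsFactors = FALSE)
}

# Levels by the recurrence level[t] = 1 + min(level[parents]), evaluated in
# topological order (parents before children).
compute_levels <- function(g) {
  alive <- names(g$parents)
  lev <- stats::setNames(rep(NA_integer_, length(alive)), alive)
  lev[g$root_id] <- 1L
  ord <- topological_order(g)
  for (id in ord) {
    if (id == g$root_id) next
    pl <- lev[g$parents[[id]]]
    if (anyNA(pl)) {
      stop_structure("term '%s' has no path to the root '%s'", id, g$root_id)
    }
    lev[id] <- 1L + min(pl)
  }
  if (anyNA(lev)) {
    stop_structure("term(s) unreachable from the root: %s",
                   paste(alive[is.na(lev)], collapse = ", "))
  }
  lev
}

# Kahn's algorithm over parent -> child direction.
topological_order <- function(g) {
  alive <- names(g$parents)
  indeg <- vapply(g$parents, length, integer(1))
  queue <- alive[indeg == 0]
  ord <- character(0)
  while (length(queue) > 0) {
    id <- queue[[1]]
    queue <- queue[-1]
    ord <- c(ord, id)
    for (ch in g$children[[id]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) != length(alive)) {
    stop_structure("ontology edge relation contains a cycle")
  }
  ord
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology_graph: %d terms (%d obsolete), root %s, max level %d\n",
              nrow(x$terms), sum(x$terms$is_obsolete), x$root_id,
              max(x$levels)))
  invisible(x)
}

check_term <- function(g, t) {
  unknown <- setdiff(t, names(g$parents))
  if (length(unknown) > 0) {
    stop_input("unknown term id(s): %s", paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

#' Ancestors of a term
#'
#' All terms reachable from `t` by repeatedly following child-to-parent
#' (`is_a`/`part_of`) edges; `t` itself is excluded.
#'
#' @param g An `ontology_graph`.
#' @param t A term id present in `g`.
#' @return Character vector of ancestor term ids (possibly empty).
#' @export
ancestors <- function(g, t) {
  check_term(g, t)
  key <- paste0("anc:", t)
  hit <- g$cache[[key]]
  if (!is.null(hit)) return(hit)
  seen <- character(0)
  frontier <- g$parents[[t]]
  while (length(frontier) > 0) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(g$parents[new], use.names = FALSE))
  }
  res <- sort(seen)
  g$cache[[key]] <- res
  res
}

#' Descendants of a term
#'
#' All terms from which `t` is reachable via child-to-parent edges — the exact
#' inverse relation of [ancestors()]; `t` itself is excluded.
#'
#' @inheritParams ancestors
#' @return Character vector of descendant term ids (possibly empty).
#' @export
descendants <- function(g, t) {
  check_term(g, t)
  key <- paste0("desc:", t)
  hit <- g$cache[[key]]
  if (!is.null(hit)) return(hit)
  seen <- character(0)
  frontier <- g$children[[t]]
  while (length(frontier) > 0) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(g$children[new], use.names = FALSE))
  }
  res <- sort(seen)
  g$cache[[key]] <- res
  res
}

#' Common ancestors of a set of terms
#'
#' The intersection over the given terms of each term's ancestor-or-self set.
#' Because the graph is rooted, the result always contains at least the root.
#'
#' @param g An `ontology_graph`.
#' @param ts Character vector of one or more term ids.
#' @return Character vector of term ids shared (as ancestor-or-self) by all
#'   of `ts`.
#' @export
common_ancestors <- function(g, ts) {
  if (length(ts) < 1) stop_input("common_ancestors() needs at least one term")
  check_term(g, ts)
  sets <- lapply(ts, function(t) c(t, ancestors(g, t)))
  Reduce(intersect, sets)
}

#' Term level
#'
#' @inheritParams ancestors
#' @return Integer level (root = 1; otherwise 1 + shortest path to the root).
#' @export
term_level <- function(g, t) {
  check_term(g, t)
  unname(g$levels[t])
}

# ancestor-or-self closure for a set of terms, as a named list
ancestor_closure <- function(g, ts) {
  stats::setNames(lapply(ts, function(t) c(t, ancestors(g, t))), ts)
}

#' Serialize an ontology graph back to OBO text
#'
#' Emits one `[Term]` stanza per term (obsolete terms flagged, edge-less),
#' re-parseable by [parse_obo()].
#'
#' @param g An `ontology_graph`.
#' @return Character vector of OBO lines.
#' @export
write_obo <- function(g) {
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(g$terms))) {
    id <- g$terms$term_id[i]
    out <- c(out, "[Term]", paste0("id: ", id),
             paste0("name: ", g$terms$name[i]))
    if (!is.na(g$terms$namespace[i])) {
      out <- c(out, paste0("namespace: ", g$terms$namespace[i]))
    }
    if (g$terms$is_obsolete[i]) {
      out <- c(out, "is_obsolete: true")
    } else {
      ps <- g$parents[[id]]
      rs <- g$relations[[id]]
      for (j in seq_along(ps)) {
        out <- c(out, if (rs[j] == "is_a") paste0("is_a: ", ps[j])
                 else paste0("relationship: part_of ", ps[j]))
      }
    }
    out <- c(out, "")
  }
  out
}

#' Dump the term table with levels as TSV
#'
#' @param g An `ontology_graph`.
#' @param path Output path.
#' @export
write_ontology_tsv <- function(g, path) {
  alive <- g$terms[!g$terms$is_obsolete, c("term_id", "name")]
  alive$level <- unname(g$levels[alive$term_id])
  write_tsv_atomic(alive, path)
}
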