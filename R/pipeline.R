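#' Assemble a pipeline run configuration
#'
#' Collects every knob of the end-to-end pipeline into one plain list that
#' serializes losslessly to YAML, so a run can be reproduced from its logged
#' configuration alone.
#'
#' @param enrichment Path to the enrichment TSV (`term_id`, `score`, optional
#'   `padj`, `genes`).
#' @param obo Path to the ontology OBO file.
#' @param score_type `"nes"` or `"overlap"`.
#' @param annotation Optional GMT/TSV path for annotation-based information
#'   content.
#' @param namespace Optional OBO namespace filter.
#' @param measure Semantic-similarity measure (default `"rel"`).
#' @param method Clustering method: `"combined"` (default), `"binary"` or
#'   `"hclust"`.
#' @param cutoff,partitioner,min_split Binary-cut parameters.
#' @param refine_threshold,max_cluster_size Combined-method refinement
#'   triggers.
#' @param linkage Hierarchical linkage.
#' @param min_cover,min_level,max_reps Representative-term parameters.
#' @param broad_level,top_k Broad-term panel parameters.
#' @param out_prefix Output path prefix; the pipeline writes
#'   `<prefix>_clusters.tsv`, `<prefix>_representatives.tsv`,
#'   `<prefix>_panel.tsv`, `<prefix>_heatmap.<format>` and
#'   `<prefix>_run.log`.
#' @param image_format `"pdf"` (default), `"png"` or `"svg"`.
#' @param seed Integer seed for every stochastic step.
#' @return A list of class `run_config`.
#' @export
run_config <- function(enrichment, obo, score_type = c("nes", "overlap"),
                       annotation = NULL, namespace = NULL,
                       measure = "rel", method = "combined",
                       cutoff = 0.85, partitioner = "pam2", min_split = 2,
                       refine_threshold = 0.5, max_cluster_size = 50,
                       linkage = "average",
                       min_cover = 2, min_level = 3, max_reps = 5,
                       broad_level = 2, top_k = 8,
                       out_prefix = "gocondense", image_format = "pdf",
                       seed = 1) {
  cfg <- list(enrichment = enrichment, obo = obo,
              score_type = match.arg(score_type),
              annotation = annotation, namespace = namespace,
              measure = measure, method = method, cutoff = cutoff,
              partitioner = partitioner, min_split = min_split,
              refine_threshold = refine_threshold,
              max_cluster_size = max_cluster_size, linkage = linkage,
              min_cover = min_cover, min_level = min_level,
              max_reps = max_reps, broad_level = broad_level, top_k = top_k,
              out_prefix = out_prefix, image_format = image_format,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with keys as in [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!all(c("enrichment", "obo") %in% names(vals))) {
    stop_input("config '%s' must set at least 'enrichment' and 'obo'", path)
  }
  do.call(run_config, vals)
}

#' Write a run configuration to YAML
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @export
write_run_config <- function(cfg, path) {
  write_atomic(path, function(tmp) {
    yaml::write_yaml(Filter(Negate(is.null), unclass(cfg)), tmp)
  })
}

#' Run the full condensation pipeline
#'
#' Enrichment table + ontology in; clustered, summarized, ranked and rendered
#' result out: similarity matrix over the significant terms, clustering by
#' the configured method, cluster ranking by mean score magnitude,
#' representative terms per cluster, broad-term panel, and an annotated
#' heatmap. All tabular outputs and the image are written atomically under
#' `cfg$out_prefix`; a run log records the resolved configuration and
#' per-stage sizes. With a fixed seed the tabular outputs are
#' byte-reproducible.
#'
#' The cluster TSV records the display order: rows are sorted by cluster rank
#' (descending mean-score magnitude) and, within a cluster, by the leaf order
#' of an average-linkage dendrogram of the cluster's submatrix, which is also
#' the heatmap row order.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, a list with the in-memory results (`table`, `S`,
#'   `assignment`, `ranks`, `representatives`, `panel`) and `paths` of the
#'   written files.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  log_lines <- c(
    "# gocondense run log",
    paste0("# started: ", format(t0, "%Y-%m-%d %H:%M:%S")),
    "# resolved config:",
    paste0("#   ", vapply(names(unclass(cfg)), function(k) {
      sprintf("%s: %s", k, paste(format(cfg[[k]]), collapse = ","))
    }, character(1))))
  stage <- function(name, ...) {
    log_lines <<- c(log_lines, sprintf("stage=%s %s elapsed=%.2fs", name,
                                       paste(..., sep = " "),
                                       as.numeric(Sys.time() - t0,
                                                  units = "secs")))
  }

  g <- parse_obo(cfg$obo, namespace_filter = cfg$namespace)
  stage("ontology", sprintf("terms=%d root=%s", length(g$parents), g$root_id))

  tab <- read_enrichment_tsv(cfg$enrichment, cfg$score_type)
  n_in <- nrow(tab)
  known <- tab$term_id %in% names(g$parents)
  if (any(!known)) {
    warning(sprintf("%d enriched term(s) absent from the ontology; excluded",
                    sum(!known)))
    tab <- tab[known, , drop = FALSE]
    attr(tab, "score_type") <- cfg$score_type
  }
  if (nrow(tab) < 2) {
    stop_input("fewer than 2 enriched terms found in the ontology")
  }
  stage("enrichment", sprintf("rows_in=%d rows_used=%d excluded=%d", n_in,
                              nrow(tab), n_in - nrow(tab)))

  ic <- if (!is.null(cfg$annotation)) {
    ann <- read_annotations(cfg$annotation)
    ann <- ann[names(ann) %in% names(g$parents)]
    information_content(g, ann)
  } else {
    information_content(g)
  }
  S <- similarity_matrix(g, tab, measure = cfg$measure, ic = ic)
  stage("similarity", sprintf("n=%d measure=%s", nrow(S), cfg$measure))

  assignment <- switch(cfg$method,
    binary = binary_cut(S, cfg$cutoff, cfg$partitioner, cfg$min_split,
                        cfg$seed),
    hclust = hierarchical_cluster(S, cfg$linkage),
    combined = combined_cluster(S, cfg$cutoff, cfg$partitioner,
                                cfg$min_split, cfg$seed,
                                cfg$refine_threshold, cfg$max_cluster_size),
    stop_input("unknown clustering method '%s'", cfg$method))
  stage("clustering", sprintf("method=%s clusters=%d", cfg$method,
                              assignment$n_clusters))

  ranks <- rank_clusters(tab, assignment)
  reps <- summarize_clusters(g, assignment, cfg$min_cover, cfg$min_level,
                             cfg$max_reps)
  panel <- broad_term_panel(g, tab$term_id, cfg$broad_level, cfg$top_k)
  stage("summarize", sprintf("representatives=%d panel=%d",
                             sum(vapply(reps, function(r) {
                               nrow(r$representatives)
                             }, integer(1))), nrow(panel)))

  ord <- display_order(S, assignment, ranks)
  paths <- list(
    clusters = paste0(cfg$out_prefix, "_clusters.tsv"),
    representatives = paste0(cfg$out_prefix, "_representatives.tsv"),
    panel = paste0(cfg$out_prefix, "_panel.tsv"),
    heatmap = paste0(cfg$out_prefix, "_heatmap.", cfg$image_format),
    log = paste0(cfg$out_prefix, "_run.log"))
  dir.create(dirname(cfg$out_prefix), showWarnings = FALSE, recursive = TRUE)

  cl_df <- data.frame(term_id = names(assignment$labels)[ord],
                      cluster = unname(assignment$labels[ord]),
                      method = assignment$method,
                      display_order = seq_along(ord),
                      score = tab$score[match(names(assignment$labels)[ord],
                                              tab$term_id)],
                      stringsAsFactors = FALSE)
  cl_df$cluster_rank <- ranks$rank[match(cl_df$cluster, ranks$cluster)]
  write_tsv_atomic(cl_df, paths$clusters)
  write_representatives_tsv(reps, paths$representatives)
  write_panel_tsv(panel, paths$panel)
  render_heatmap(S, assignment, ranks, reps, panel, g,
                 file = paths$heatmap, format = cfg$image_format)
  stage("render", sprintf("file=%s", paths$heatmap))

  write_atomic(paths$log, function(tmp) writeLines(log_lines, tmp))
  invisible(list(table = tab, S = S, assignment = assignment, ranks = ranks,
                 representatives = reps, panel = panel, paths = paths))
}

# Heatmap/display row order: clusters by rank, members by average-linkage
# dendrogram leaf order within each cluster.
display_order <- function(S, assignment, ranks) {
  ord <- integer(0)
  for (k in ranks$cluster) {
    idx <- which(assignment$labels == k)
    if (length(idx) > 2) {
      hc <- stats::hclust(stats::as.dist(1 - S[idx, idx, drop = FALSE]),
                          method = "average")
      idx <- idx[hc$order]
    }
    ord <- c(ord, unname(idx))
  }
  ord
}

#' Render the annotated similarity heatmap
#'
#' One image: the similarity heatmap with rows/columns grouped into cluster
#' blocks in rank order, each cluster labeled on the right with its top
#' representative term (falling back to the cluster index when a cluster has
#' no named representative), and a top panel of broad ontology terms, each
#' labeled with the percentage of input terms it covers.
#'
#' @param S Similarity matrix.
#' @param assignment A `cluster_assignment` over the terms of `S`.
#' @param ranks Output of [rank_clusters()].
#' @param reps Output of [summarize_clusters()].
#' @param panel Output of [broad_term_panel()].
#' @param g The `ontology_graph` (for broad-term membership of each column).
#' @param file Output image path.
#' @param format `"pdf"`, `"png"` or `"svg"`.
#' @param max_display Refuse to render more terms than this (default 2000);
#'   pre-filter the enrichment table instead of downsampling silently.
#' @param max_slices With more clusters than this (default 40) the heatmap is
#'   drawn unsplit — slice layout cost grows quadratically in the number of
#'   blocks — with a cluster color bar on the right instead of per-block
#'   labels.
#' @return Invisibly, `file`.
#' @export
render_heatmap <- function(S, assignment, ranks, reps, panel, g = NULL,
                           file = "heatmap.pdf",
                           format = c("pdf", "png", "svg"),
                           max_display = 2000, max_slices = 40) {
  format <- match.arg(format)
  n <- nrow(S)
  if (n > max_display) {
    stop_input(paste("refusing to render %d terms (max %d);",
                     "pre-filter the enrichment table"), n, max_display)
  }
  ord <- display_order(S, assignment, ranks)
  ids <- rownames(S)[ord]
  split <- factor(assignment$labels[ord],
                  levels = ranks$cluster)

  # one right-side label per cluster: top representative name, else index
  cl_label <- vapply(as.character(ranks$cluster), function(k) {
    r <- reps[[k]]$representatives
    if (nrow(r) > 0 && !is.na(r$name[1]) && nzchar(r$name[1])) {
      sprintf("%s: %s", k, r$name[1])
    } else k
  }, character(1))

  top_anno <- NULL
  if (!is.null(g) && nrow(panel) > 0) {
    clo <- ancestor_closure(g, ids)
    memb <- vapply(panel$term_id, function(b) {
      as.integer(vapply(clo, function(cl) b %in% cl, logical(1)))
    }, integer(length(ids)))
    memb <- matrix(memb, nrow = length(ids),
                   dimnames = list(ids, sprintf("%s (%.1f%%)", panel$name,
                                                panel$percentage)))
    top_anno <- ComplexHeatmap::HeatmapAnnotation(
      df = as.data.frame(memb == 1),
      col = stats::setNames(lapply(colnames(memb), function(x) {
        c(`TRUE` = "#2166ac", `FALSE` = "#f7f7f7")
      }), colnames(memb)),
      show_legend = FALSE,
      annotation_name_side = "left",
      annotation_name_gp = grid::gpar(fontsize = 6))
  }

  common <- list(
    name = "similarity",
    col = grDevices::colorRampPalette(c("#f7f7f7", "#d6604d", "#67001f"))(64),
    cluster_rows = FALSE, cluster_columns = FALSE,
    row_title = NULL, column_title = NULL,
    show_row_names = n <= 60, show_column_names = FALSE,
    row_names_gp = grid::gpar(fontsize = 5),
    border = TRUE,
    top_annotation = top_anno)
  ht <- if (assignment$n_clusters <= max_slices) {
    do.call(ComplexHeatmap::Heatmap, c(list(
      S[ord, ord],
      row_split = split, column_split = split,
      right_annotation = ComplexHeatmap::rowAnnotation(
        cluster = ComplexHeatmap::anno_block(
          labels = cl_label,
          labels_gp = grid::gpar(fontsize = 7),
          labels_rot = 0,
          width = grid::unit(6, "cm")))), common))
  } else {
    pal <- grDevices::rainbow(assignment$n_clusters)
    do.call(ComplexHeatmap::Heatmap, c(list(
      S[ord, ord],
      right_annotation = ComplexHeatmap::rowAnnotation(
        cluster = ComplexHeatmap::anno_simple(
          as.character(split),
          col = stats::setNames(pal, levels(split))),
        annotation_name_gp = grid::gpar(fontsize = 7))), common))
  }

  open_dev <- switch(format,
    pdf = function(f) grDevices::pdf(f, width = 11, height = 8),
    png = function(f) grDevices::png(f, width = 2200, height = 1600,
                                     res = 200),
    svg = function(f) grDevices::svg(f, width = 11, height = 8))
  write_atomic(file, function(tmp) {
    open_dev(tmp)
    on.exit(grDevices::dev.off())
    ComplexHeatmap::draw(ht)
  })
  invisible(file)
}
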