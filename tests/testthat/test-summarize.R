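test_that("enrichment_table enforces score semantics", {
  expect_s3_class(enrichment_table(c("a", "b"), c(1.5, 2.2), "nes"),
                  "enrichment_table")
  expect_s3_class(enrichment_table(c("a", "b"), c(-1.5, -2.2), "nes"),
                  "enrichment_table")
  expect_error(enrichment_table(c("a", "b"), c(1.5, -2.2), "nes"),
               "mixed-sign")
  expect_error(enrichment_table(c("a", "a"), c(1, 2), "nes"), "duplicated")
  expect_error(enrichment_table(c("a", "b"), c(0.5, 1.2), "overlap"),
               "\\[0, 1\\]")
  tab <- enrichment_table(c("a", "b"), c(0.5, 1), "overlap",
                          padj = c(0.01, 0.04), genes = list("g1", c("g2", "g3")))
  expect_equal(attr(tab, "score_type"), "overlap")
  expect_equal(tab$genes[[2]], c("g2", "g3"))
})

test_that("representative selection: singleton, shared ancestor, no candidate", {
  g <- parse_obo(diamond_obo)   # levels: R=1, a=b=2, c=3, d=3
  # singleton cluster self-represents (min_cover 2 cannot be met)
  rs <- representative_terms(g, "X:d")
  expect_equal(rs$representatives$term_id, "X:d")
  expect_equal(rs$representatives$covered[[1]], "X:d")

  # deep shared ancestor wins over shallow ones
  deep <- c("[Term]", "id: D:r", "",
            "[Term]", "id: D:1", "is_a: D:r", "",
            "[Term]", "id: D:2", "is_a: D:1", "",
            "[Term]", "id: D:3", "is_a: D:2", "",   # level 4
            "[Term]", "id: D:x", "is_a: D:3", "",
            "[Term]", "id: D:y", "is_a: D:3", "")
  gd <- parse_obo(deep)
  rs2 <- representative_terms(gd, c("D:x", "D:y"), min_cover = 2,
                              min_level = 3)
  expect_equal(rs2$representatives$term_id, "D:3")
  expect_equal(unname(rs2$representatives$level), 4L)
  expect_setequal(rs2$representatives$covered[[1]], c("D:x", "D:y"))
  expect_false(rs2$representatives$is_member[1])

  # members sharing only the root with min_level 2: both self-represent
  sib <- parse_obo(c("[Term]", "id: S:r", "", "[Term]", "id: S:a",
                     "is_a: S:r", "", "[Term]", "id: S:b", "is_a: S:r", ""))
  rs3 <- representative_terms(sib, c("S:a", "S:b"), min_cover = 2,
                              min_level = 2)
  expect_equal(sort(rs3$representatives$term_id), c("S:a", "S:b"))
  expect_true(all(rs3$representatives$self_rep))
  expect_error(representative_terms(sib, character(0)), "non-empty")
})

test_that("representative covering partitions the cluster on random fixtures", {
  for (seed in 1:15) {
    g <- random_dag(sample(15:40, 1), seed = 200 + seed)
    ids <- names(g$parents)
    members <- gocondense:::with_seed(seed, sample(ids, sample(3:8, 1)))
    rs <- representative_terms(g, members)
    covered <- unlist(rs$representatives$covered)
    expect_setequal(covered, members)
    expect_equal(anyDuplicated(covered), 0)
  }
})

test_that("greedy selection agrees with the brute-force re-enumeration oracle", {
  for (seed in 1:20) {
    g <- random_dag(sample(15:40, 1), seed = 300 + seed)
    ids <- names(g$parents)
    members <- gocondense:::with_seed(seed, sample(ids, sample(2:10, 1)))
    rs <- representative_terms(g, members, min_cover = 2, min_level = 3,
                               max_reps = 5)
    or <- oracle_representatives(g, members, min_cover = 2, min_level = 3,
                                 max_reps = 5)
    expect_equal(rs$representatives$term_id, or$term_id)
    for (i in seq_along(or$covered)) {
      expect_setequal(rs$representatives$covered[[i]], or$covered[[i]])
    }
  }
})

test_that("raising min_level never increases first-pick coverage", {
  for (seed in 1:10) {
    g <- random_dag(30, seed = 400 + seed)
    members <- gocondense:::with_seed(seed,
                                      sample(names(g$parents), 6))
    cover_at <- function(ml) {
      r <- representative_terms(g, members, min_cover = 1, min_level = ml)
      r$representatives$n_covered[1]
    }
    expect_true(cover_at(3) <= cover_at(2))
    expect_true(cover_at(4) <= cover_at(3))
  }
})

test_that("broad panel percentages follow descendant-or-self counting", {
  # root with broad terms B1, B2; B1 has 3 leaves, B2 has 2; one leaf under both
  obo <- c("[Term]", "id: P:r", "name: root", "",
           "[Term]", "id: P:B1", "name: broad one", "is_a: P:r", "",
           "[Term]", "id: P:B2", "name: broad two", "is_a: P:r", "",
           "[Term]", "id: P:l1", "is_a: P:B1", "",
           "[Term]", "id: P:l2", "is_a: P:B1", "",
           "[Term]", "id: P:l3", "is_a: P:B1", "is_a: P:B2", "",
           "[Term]", "id: P:l4", "is_a: P:B2", "")
  g <- parse_obo(obo)
  panel <- broad_term_panel(g, c("P:l1", "P:l2", "P:l3", "P:l4", "P:B2"))
  expect_equal(panel$percentage[panel$term_id == "P:B1"], 60)   # 3 of 5
  # B2: l3, l4 and B2 itself (descendant-or-self) = 3 of 5
  expect_equal(panel$percentage[panel$term_id == "P:B2"], 60)
  # multi-parent leaf counts toward both panels
  p2 <- broad_term_panel(g, "P:l3")
  expect_setequal(p2$term_id, c("P:B1", "P:B2"))
  expect_equal(p2$percentage, c(100, 100))
  # order invariance
  p3 <- broad_term_panel(g, rev(c("P:l1", "P:l2", "P:l3", "P:l4", "P:B2")))
  expect_equal(p3, panel)
  expect_error(broad_term_panel(g, "P:l1", broad_level = 1), ">= 2")
  expect_error(broad_term_panel(parse_obo(c("[Term]", "id: Z:r", "")),
                                "Z:r"), "no term at level")
})

test_that("rank_clusters orders by |mean| with size and index tie-breaks", {
  mk <- function(labels) {
    structure(list(labels = labels, n_clusters = max(labels),
                   method = "binary"), class = "cluster_assignment")
  }
  tab <- enrichment_table(letters[1:5], c(2.5, 2.5, 1.2, 1.2, 1.2), "nes")
  a <- mk(setNames(c(1L, 1L, 2L, 2L, 2L), letters[1:5]))
  r <- rank_clusters(tab, a)
  expect_equal(r$cluster, c(1, 2))
  expect_equal(r$mean_score, c(2.5, 1.2))

  # negative NES: most negative mean first
  tabn <- enrichment_table(letters[1:4], c(-2.5, -2.5, -1.2, -1.2), "nes")
  an <- mk(setNames(c(1L, 1L, 2L, 2L), letters[1:4]))
  rn <- rank_clusters(tabn, an)
  expect_equal(rn$mean_score, c(-2.5, -1.2))

  # equal means: larger cluster first
  tabt <- enrichment_table(letters[1:8], rep(2, 8), "nes")
  at <- mk(setNames(c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L), letters[1:8]))
  rt <- rank_clusters(tabt, at)
  expect_equal(rt$cluster, c(2, 1))
  expect_equal(rt$size, c(5, 3))

  expect_error(rank_clusters(tab, mk(setNames(c(1L, 2L), c("a", "zz")))),
               "missing from the enrichment table.*zz")
})

test_that("summaries and panels export as TSV", {
  g <- random_dag(40, seed = 500)
  fxids <- names(g$parents)[1:12]
  a <- structure(list(labels = setNames(rep(1:3, each = 4), fxids),
                      n_clusters = 3L, method = "binary"),
                 class = "cluster_assignment")
  reps <- summarize_clusters(g, a)
  expect_length(reps, 3)
  path <- tempfile(fileext = ".tsv")
  write_representatives_tsv(reps, path)
  df <- read.delim(path)
  expect_true(all(c("cluster", "rank", "term_id", "n_covered",
                    "covered_ids") %in% names(df)))
  # every member appears in exactly one covered set per cluster
  for (k in 1:3) {
    cov <- unlist(strsplit(df$covered_ids[df$cluster == k], ","))
    expect_setequal(cov, names(a$labels)[a$labels == k])
  }

  panel <- broad_term_panel(g, fxids)
  p <- tempfile(fileext = ".tsv")
  write_panel_tsv(panel, p)
  expect_equal(read.delim(p)$term_id, panel$term_id)
})
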