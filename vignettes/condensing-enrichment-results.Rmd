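---
title: "Condensing GO enrichment results: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condensing GO enrichment results: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gocondense)
```

## The problem

A GSEA or ORA run against the Gene Ontology Biological Process branch
routinely returns hundreds of significant terms. GO is deliberately
redundant — a specific process is annotated alongside its parents,
grandparents and overlapping siblings — so the raw list is dominated by
near-duplicates, and the common workaround of reporting the top ten terms
discards most of the signal. `gocondense` reduces such a list to a small
number of *ranked clusters of semantically similar terms*, each labeled by
whole, readable ontology terms rather than keyword fragments, together with
a panel of broad terms that situates the result in the ontology's top
level.

The pipeline is: semantic similarity matrix over the significant terms →
clustering → per-cluster representative terms via common ancestors →
cluster ranking by enrichment score → annotated heatmap.

## Ontology model

The engine accepts any rooted DAG in OBO format; it is not hard-wired to
GO. Both `is_a` and `relationship: part_of` edges count for ancestry and
levels, matching the transitive backbone of the basic GO release; other
relations (`regulates`, `occurs_in`) are ignored. Obsolete terms are kept
in the term table but carry no edges.

**Levels.** The root has level 1 and every term has level
`1 + min(level(parents))` — one plus the *shortest* path to the root. The
shortest-path convention is the common one for GO and makes "broad" terms
small-level; nothing downstream depends on more than the ordering of
levels, but the choice is visible in which candidate wins representative
selection when paths of different lengths coexist. A full-GO file with its
three namespace roots is handled by the `namespace_filter` argument of
`parse_obo()`; the engine itself requires exactly one root and rejects
anything cyclic.

## Semantic similarity

The published description of the method this package re-derives does not
name its similarity measure, so the measure is a configurable parameter
with a documented default rather than a fixed constant.

Information content is `ic(t) = -ln p(t)` (nats). With a term-to-gene
annotation map, `p(t)` is the fraction of the annotated gene corpus
attached to `t` or any descendant (a zero-count term gets a pseudo-count of
1, with a warning). Without annotations — the default, so the tool runs
with no external corpus — the structural surrogate
`p(t) = (|descendants(t)| + 1) / N` is used. Both give `ic(root) = 0` and
IC non-decreasing toward the leaves.

Four measures are available, all symmetric and bounded in `[0, 1]`, with
MICA the most informative common ancestor:

* `rel` (default) — Schlicker relevance,
  `2·ic(MICA)/(ic(t1)+ic(t2)) · (1 − e^{−ic(MICA)})`. Chosen as the default
  because it is the convention of the clustering tool this package improves
  upon, and because the relevance factor damps pairs whose only shared
  ancestry is near the root.
* `lin` — the Lin ratio without the damping factor.
* `resnik_norm` — `ic(MICA)` divided by the ontology-wide maximum IC.
* `jaccard_anc` — Jaccard index of ancestor-or-self closures; needs no IC.

Duplicated term ids in the input are an error rather than being collapsed:
duplicates almost always indicate an upstream join bug, and silently
deduplicating would hide it.

## Clustering

**Binary cut.** The similarity matrix is recursively bisected. A submatrix
is accepted as a cluster when its score — the mean off-diagonal similarity;
1 for a single term — reaches `cutoff`, or when it is smaller than
`min_split`. Otherwise its terms are split in two by PAM (default) or
k-means with k = 2 applied to the *rows* of the submatrix: each term's
similarity profile is its feature vector. Partitioning profiles rather than
raw pairwise distances is what keeps a block coherent when the recursion
must send two of three blocks one way — the third block's members share a
profile even though their distances to the other blocks are noisy. The
default `cutoff = 0.85` suits semantic-similarity matrices, where genuinely
redundant term groups are very tight.

**Hierarchical.** Average-linkage (or complete) agglomeration on
`1 − S`; when `k` is not given it maximizes the mean silhouette width over
`k = 2..min(n−1, 25)`, ties to the smallest `k`. The degenerate two-term
matrix takes `k = 2`.

**Combined.** Binary cut first; then every stage-1 cluster that is *loose*
(within-cluster mean similarity `< refine_threshold`, default 0.5) or
*oversized* (`> max_cluster_size` members, default 50) is re-clustered
hierarchically within its own submatrix. Tight, reasonably sized clusters
pass through untouched, so on well-separated input the combined method
reproduces binary cut exactly — a metamorphic identity the test suite
checks. The published account defers the combined method's exact triggers
to unavailable supplementary material; the loose/oversized pair used here
is this package's own definition, selected to interpolate between its two
parents, and both thresholds are exposed.

**Separation.** The difference score of a clustering is
`mean(within-cluster pair similarity) − mean(between-cluster pair
similarity)`; singleton clusters contribute no within-pairs, and an
all-singleton clustering defines the within-mean as 0. The formula is fixed
for this package (the source description does not print one) and is used
consistently by `benchmark_methods()`, which tabulates the three methods
over a fixture list and reports paired Wilcoxon signed-rank statistics for
each method pair. Whether a lower or higher score is "better" depends on
how a method trades cluster tightness against cluster count, so the
benchmark reports distributions without asserting a direction. On
well-separated synthetic fixtures the combined method equals binary cut
(no trigger fires), making that comparison degenerate; the benchmark flags
it (`degenerate = TRUE`, p = 1) instead of manufacturing a difference.

Determinism: tie-breaks are everywhere resolved by input term order,
cluster indices are relabeled by first appearance, and every stochastic
step (PAM build order, k-means starts, fixture draws) runs under an
explicit seed that is restored afterwards.

## Representative terms

A cluster is labeled by the most specific common ancestors that cover it,
selected greedily. Candidates for the still-uncovered member set are every
ancestor-or-self of an uncovered member with level `≥ min_level` covering
`≥ min_cover` uncovered members; the deepest candidate wins, ties going to
larger coverage, then the lexicographically smallest id. Covered members
are removed and the loop repeats until the cluster is covered, no candidate
qualifies, or `max_reps` picks have been made; leftovers self-represent, so
the covering sets always partition the cluster.

"Most specific" (deepest) is the deliberate reading of "highest-level
ancestor": the point of the exercise is escaping overly general labels, and
a deepest-first priority yields terms like *regulation of viral life cycle*
rather than *regulation*. `min_cover = 2` stops the greedy loop from
labeling with a single member's private ancestor; `min_level = 3` excludes
the root and its immediate children, which are too generic to label
anything. A representative may be a pure ancestor outside the input set;
the output marks this (`is_member`).

## Broad-term panel and ranking

The panel lists ontology terms at `broad_level` (default 2 — direct
children of the root, the "immune system process"/"metabolic process"
stratum in GO), each labeled with the percentage of input terms that are
the broad term itself or one of its descendants. Multi-parentage means one
input term can count toward several panel entries, so percentages need not
sum to 100. The `top_k` (default 8) entries by percentage are kept.

Clusters are ranked by descending `|mean score|` (ties: larger cluster,
then smaller index). The magnitude is used so a negative-NES analysis
ranks its most strongly down-regulated cluster first; sign never mixes
within one run because the input contract rejects mixed-sign NES tables —
up- and down-regulated term sets are condensed in separate invocations,
which keeps the clustering substrate homogeneous instead of silently
splitting inside one plot.

## Gene-set overlap analysis

`overlap_matrix()` compares two GMT collections:
`values[i, j] = |A_i ∩ B_j| / |A_i|`, the proportion of the *row* set's
genes found in the column set. Row-relative orientation is deliberate — the
question is how much of each ontology-derived set is contained in, say, a
Hallmark set — and is recorded in the exported TSV header.
`inclusion_calls()` flags row sets whose best column overlap reaches a
threshold (default 0.8, `>=` at the boundary); "included within" implies
predominant containment, but no canonical cutoff exists, so it is exposed
on the CLI. Gene matching is exact string comparison with an optional
case-folding flag; no symbol aliasing is attempted.

## The synthetic generators, and what passing tests mean

Three generators make every module testable offline:

* `synth_dag()` — random rooted DAGs built in level order, each non-root
  term taking one parent from the level above plus up to `max_parents − 1`
  parents from any shallower level, so diamonds and divergent path lengths
  arise; edges are 80% `is_a` / 20% `part_of`. The generator emits OBO text
  and parses it back, so round-trip fidelity is built into its contract.
* `synth_similarity()` — planted-block matrices with within-block entries
  drawn from `within_range` (default `(0.75, 0.95)`) and cross-block
  entries from `between_range` (default `(0, 0.15)`). The constructor
  rejects `within.lo ≤ between.hi`, keeping recovery tests well-posed. For
  clustering runs on these fixtures the binary-cut cutoff is set to 0.7 —
  below the within-block floor and far above the cross-block ceiling — since
  the default 0.85 is calibrated to tight semantic-similarity blocks, not
  to this draw regime.
* `synth_enrichment()` — term samples with NES drawn from `±[1.2, 3]`
  (magnitudes typical of significant GSEA hits) or ORA overlap proportions
  from `(0, 1]`.

These fixtures emulate the *structure* the algorithms operate on, not real
data's texture: a real GO slice has heavy-tailed branching, correlated
similarity blocks of very unequal tightness, and annotation-driven IC;
block boundaries in real matrices are nowhere as crisp as the enforced
separation here. Passing the planted-recovery tests therefore shows the
clustering machinery is correct, not that any particular cutoff is optimal
for a given real dataset.

## Numerical choices and degenerate inputs

Matrix validation tolerates `1e-8` asymmetry and `1e-12` range violations
(floating-point symmetrization artifacts), and similarity values are
clamped to `[0, 1]` after computation. Two-term submatrices are split
directly (PAM needs `k < n`). A partitioner that returns one group (rare
k-means degeneracy) terminates that recursion branch instead of looping. An
all-singleton stage-1 result passes through refinement untouched. The
acyclicity check runs before level computation so cycles are reported as
such rather than as unreachable terms.

Rendering uses `ComplexHeatmap` with rows and columns ordered by cluster
rank and, within a cluster, by average-linkage leaf order. Slice-based
block layout is quadratic in the number of slices, so block-split rendering
with per-cluster representative labels is used up to 40 clusters; beyond
that the heatmap is drawn unsplit with a cluster color bar. Above 2000
terms rendering is refused outright with a pointer to pre-filtering. The
default output is PDF (vector, device-independent); PNG and SVG are
options.

## Problem sizes in the shipped tests

The test suite verifies oracle equivalence on 100 random DAGs of up to 50
terms (graph layer) and 100 DAGs of 6–16 terms at all-pairs resolution
(similarity layer), planted recovery on 100 matrices of up to 80 terms,
representative-selection oracle agreement on 100 DAG/cluster fixtures, a
50-fixture benchmark, and one 277-term end-to-end run executed twice to
assert byte-identical tabular output. These sizes exercise every code path
while keeping a full run of suite plus acceptance script to a few minutes
on a single core.

## Limitations

The engine requires an explicitly hierarchical ontology; flat collections
(Hallmark, KEGG) can be *compared against* via the overlap module but not
condensed. There is no term-replacement (`replaced_by`) handling, no OWL
input, no Wang-style graph similarity, and no gene-level between-product
similarity. The similarity measure and IC source are defaults, not facts
about the method's published description, and should be stated when
reporting results.
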