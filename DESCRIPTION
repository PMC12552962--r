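Package: gocondense
Title: Condense Gene Ontology Enrichment Results into Ranked, Representative Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summarizes large sets of enriched Gene Ontology Biological
    Process terms into interpretable, ranked clusters. Builds a semantic
    similarity matrix over the significant terms, clusters it with binary
    cut, agglomerative hierarchical clustering, or a combined method
    (binary cut followed by hierarchical refinement of loose or oversized
    clusters), labels each cluster with representative terms chosen as the
    deepest common ancestors that cover its members, annotates the result
    with a panel of broad ontology terms, and ranks clusters by mean
    normalized enrichment score or gene-overlap proportion. Also provides
    GMT gene-set handling with cross-collection overlap analysis, a
    synthetic-fixture generator (random rooted DAGs, planted-block
    similarity matrices, synthetic enrichment tables), a clustering
    benchmark, and an annotated heatmap rendering of the condensed result.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    igraph,
    stats,
    utils,
    grDevices,
    grid,
    yaml,
    optparse,
    ComplexHeatmap
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    jsonlite
Config/testthat/edition: 3
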