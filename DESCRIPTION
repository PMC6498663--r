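Package: comethnet
Title: RNA Co-Methylation Networks for Functional Annotation of m6A Sites
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds RNA co-methylation networks from site-by-condition m6A
    methylation-level matrices derived from MeRIP-Seq IP/Input experiments,
    and predicts biological functions of individual methylation sites by
    guilt-by-association. Edges join site pairs whose Spearman correlation
    ranks in the extreme tails and survives Bonferroni-adjusted Fisher
    asymptotic testing. Hub sites (more than three neighbours) are annotated
    by GO biological-process enrichment of their neighbours' host genes
    reduced to GO-slim terms; network modules found with a from-scratch
    Markov Cluster (MCL) implementation are annotated by within-module
    enrichment. Predictions are benchmarked against a degree-preserving
    edge-rewiring null, with recall/precision evaluated over PV (enrichment
    p-value) and GN (term count) cutoff grids. Includes seeded synthetic-data
    generators (planted co-methylation modules, toy ontology, IP/Input count
    simulation) so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    ape,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
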