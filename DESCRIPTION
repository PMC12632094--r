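Package: clsmeta
Title: Meta-Analysis of Genome-Wide Chronological Lifespan Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integrates heterogeneous genome-wide gene-deletion chronological
    lifespan (CLS) screens into a consensus longevity ranking using PROMETHEE II
    outranking with ROC-derived dataset weights. Quantifies inter-screen
    concordance (Spearman matrices, tail Jaccard overlap) and models its
    experimental drivers, characterizes the consensus rank with rank-distribution
    and preranked gene-set enrichment statistics, associates transcription
    factors with enriched functional clusters, and estimates relative lifespans
    from competitive-aging fluorescence assays. A synthetic-data generator with
    recorded ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
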