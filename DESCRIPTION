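Package: aggdev
Title: Horizontal Gene Transfer Screening and Developmental Expression
    Analysis for Aggregative Multicellularity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Inference machinery for comparative genomics of aggregative
    multicellularity in amoebae: taxonomy-partitioned screening of homology
    hit tables for horizontal gene transfer (HGT) candidates, gene-tree
    sister-clade HGT calling with bootstrap-support thresholds and family
    monophyly classification, a conservative single-replicate posterior
    log2 fold-change estimator with stage-response set classification
    (Aggup/Aggdn/Germup/Germdn/aggregation-specific), orthology-group and
    functional-profile set summaries, and a synthetic-data module that
    plants ground truth (trees with known donors, hit profiles, negative
    binomial count matrices, annotation and orthology tables) so every
    stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
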