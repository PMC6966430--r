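Package: omicscore
Title: Hierarchical Pathway Enrichment and Combined Gene Scoring for
    Cross-Platform Omics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Global omics analysis of cross-platform differential
    expression: fold-change DEG selection from microarray-like (log2) and
    RNA-seq-like (linear FPKM) matrices, directional hypergeometric
    pathway enrichment with z-score transformation, meta-z aggregation
    over a system/subsystem/pathway hierarchy, combined gene-prioritization
    scores (MCS and ARCS) with precision-at-k benchmarking against a
    disease-gene gold standard, cross-platform Jaccard concordance,
    Euclidean clustering of condition profiles, an efficiency-adjusted
    comparative-Ct calculator, and a seeded synthetic-data generator with
    planted pathway effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
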