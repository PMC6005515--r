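Package: poolscreen
Title: Pooled CRISPR Drug-Sensitizer Screen Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of pooled CRISPR knockout drug-sensitizer screens:
    guide-level count import and low-count filtering, TMM normalization and
    precision-weighted empirical-Bayes moderated statistics for differential
    guide abundance, gene-level median log-fold-change aggregation and hit
    calling, cross-arm hit overlap, and a Bliss-style drug-by-gene combination
    score for pooled, arrayed and siRNA validation data. Includes a
    negative-binomial screen simulator and an arrayed-plate simulator with
    known planted effects so every pipeline stage can be verified by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: CRISPR, PooledScreens, FunctionalGenomics, Normalization,
    DifferentialExpression, Software
RoxygenNote: 7.3.3
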