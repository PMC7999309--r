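Package: cytopi
Title: Differential Proteomics with Pi-Score Ranking and Network-Based
    Cytokine Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A label-free proteomics analysis pipeline for case/control
    abundance matrices, built around urinary-exosome studies of
    vancomycin-associated acute kidney injury. Implements two-step
    median-anchored abundance normalization, per-protein Welch testing
    with pi-score (fold-change times significance) ranking and
    classification, Bray-Curtis dissimilarity with principal coordinates
    analysis and PERMANOVA permutation testing, and a network-based
    cytokine inference that scores the enrichment of cytokine connections
    to case- versus control-associated proteins in a STRING-style
    interaction network. Ships a synthetic-data generator with planted
    differential proteins and cytokine connectivity so every stage is
    testable against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
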