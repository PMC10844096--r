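Package: tfhlscape
Title: Single-Cell Analytics for T-Follicular-Helper Lymphoma Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of the bespoke single-cell analytics
    used in T-follicular-helper lymphoma (TFHL) profiling: TCR-clonotype
    tumor-cell calling with single-chain classification, per-cell somatic
    mutation genotyping under allelic dropout, expression-based copy-number
    inference with subclone trees, rank-based per-cell signature scoring and
    Wilcoxon differential expression, a tumor-specific marker discovery
    cascade, repertoire overlap indices, spatial neighborhood permutation
    tests for imaging mass cytometry, and ligand-receptor crosstalk scoring.
    Ships a synthetic-data generator that plants known clones, copy-number
    events, mutations, markers and spatial structure so every stage is
    testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
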