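Package: npxbio
Title: Plasma Proteome Biomarker Discovery for Olink NPX Panel Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted plasma proteomics measured by
    proximity extension assay and reported as NPX (log2 normalized protein
    expression). Covers NPX import and preprocessing (cross-panel duplicate
    assay resolution, below-LOD flagging, iterative-PCA imputation of missing
    values), principal component analysis with a permutation test of
    group-centroid separation, per-protein Welch tests with Benjamini-Hochberg
    false discovery rate control, an all-relevant shadow-feature (Boruta-style)
    random-forest selector, age-adjusted binary logistic biomarker models with
    odds ratios, concordance indexes and nested likelihood-ratio tests, and
    summarization of annotated single-cell expression into dot-plot statistics
    for cell-type assignment of candidate biomarkers. Includes a synthetic
    cohort generator with the statistical structure these methods assume, so
    the whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
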