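Package: ctcmarkers
Title: Marker Discovery Cascade and Detection Statistics for Circulating
    Tumor Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: An in silico pipeline for prioritizing immunocytochemistry
    markers of circulating tumor cells (CTCs) in breast cancer, and for
    scoring the efficiency of the resulting marker cocktails. Implements a
    moderated t-statistic with Benjamini-Hochberg false discovery rate
    control for tumor versus adjacent-tissue differential expression, the
    "overmean" expressed-and-variable gene selector for heterogeneous cell
    line panels and sparse single-cell matrices, auto/cross-covariance
    (ACC) protein descriptors with a trainable antigenicity head, a
    three-criterion in silico sort (membrane localization, immune-cell
    exclusion, immunohistochemistry level), rule-based atypical-cell and
    CTC calling from per-cell morphology and staining features, and cohort
    positivity statistics with paired and unpaired Student t-tests. A
    synthetic-data generator emulating the statistical structure of the
    study inputs makes the whole cascade testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    glmnet,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
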