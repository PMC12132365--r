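Package: senotyper
Title: Senotyping and the Quiescence-Senescence Continuum in Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for chemotherapy-induced cell-cycle withdrawal
    measured by single-cell RNA-seq and live-cell reporter imaging. Provides
    quality-control filtering, log-normalization, highly-variable-gene
    selection and PCA, binned-control gene module scoring, cell-cycle phase
    assignment, shared-nearest-neighbor Leiden clustering, Wilcoxon
    differential expression with the ranking score avg_log2FC x
    -log10(adjusted p), native preranked gene set enrichment with
    leading-edge extraction, principal-graph (MST over cluster centroids)
    pseudotime with branch splitting and Loess score gradients, derivation of
    a shared SASP gene set and an etoposide-induced senescence signature,
    CDK2 activity trace classification, reporter-accumulation slope
    estimation, DNA-content 2N/4N saddle splitting, and a seeded synthetic
    data generator that plants a quiescence-senescence continuum with ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    uwot
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    yaml,
    mclust,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
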