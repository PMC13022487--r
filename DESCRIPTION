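Package: proteoseg
Title: Unsupervised Segmentation of Plasma Proteomic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised segmentation of high-dimensional plasma-proteomic
    cohorts with structured missingness, and the downstream disease-association
    analyses that characterize the resulting participant clusters. Implements
    two complementary clustering paths: DIRAM (missingness-pattern grouping
    into complete subdatasets, two-dimensional UMAP embedding, density-based
    cluster detection with size bounds, and a cross-subdataset overlap merge
    rule) and DIRCOD (nearest-neighbour imputation, iterated Leiden community
    detection with per-iteration differential-protein selection validated on
    the raw non-imputed matrix, and co-assignment pattern clustering).
    Downstream tools include a conservative quartile rule for calling high/low
    protein abundance per cluster, percentile-slicing cluster recreation with
    leave-one-out odds-ratio curves, principal-axis prevalence gradients,
    differential coregulation matrices with Bonferroni critical correlations,
    and per-cluster demographic and ICD-10 enrichment characterization. A
    synthetic cohort generator with planted clusters, block-structured
    missingness and cluster-dependent disease prevalence makes every stage
    testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    igraph,
    uwot,
    RANN,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
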