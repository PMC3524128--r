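Package: microCNA
Title: Micro-Aberration Analysis of High-Density Tiling aCGH Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterises copy-number micro-aberrations
    (focal events spanning fewer than 64 contiguous tiling probes,
    roughly 15 kb) in gene-centric high-density array-CGH profiles.
    Provides change-point segmentation of per-gene log2 ratio profiles,
    micro versus macro aberration calling, quadrant and promoter
    positional analysis within genes, integration with gene expression
    (concordance rates, pooled Fisher exact tests, per-gene ANOVA), a
    scan-statistic chance model for expected micro-aberration counts
    with gene-size correction, Kaplan-Meier stratification by
    micro-aberration burden, and a seeded synthetic-cohort generator
    with recorded ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
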