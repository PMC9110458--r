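Package: triomics
Title: Three-Way Tensor Decomposition and Weighted Co-Expression
    Analysis of Multi-Factor Transcriptomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing gene expression measured across two
    crossed experimental factors, such as genotypes and developmental
    stages of the sugarcane culm.  Implements Tucker3 three-way principal
    component analysis of a genotype x gene x stage expression tensor via
    alternating least squares with higher-order SVD initialisation,
    model-size selection over a component grid, core-element variance
    partitioning and main-effect attribution; weighted co-expression
    network construction (soft-threshold selection by scale-free fit,
    unsigned adjacency, topological overlap, module detection, module
    eigengenes and module-trait statistics); count normalisation and
    filtering (trimmed mean of M-values, counts per million, prevalence
    filters); trait-specific candidate-gene selection; and a
    synthetic-data generator with known planted structure for validating
    the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
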