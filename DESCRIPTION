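Package: metbiom
Title: Multi-Environment Trial Biometry for Crop Genotype Evaluation
Version: 0.1.0
Authors@R: person("MET", "Biometry Team", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A complete biometry pipeline for balanced multi-environment
    crop trials laid out as randomized complete block designs (RCBD):
    per-environment analysis of variance with moment estimation of
    genotypic, environmental and phenotypic variance components; the
    derived genetic-parameter suite (coefficients of variation,
    broad-sense heritability, genetic advance and genetic gain);
    genotypic and phenotypic trait correlations from mean cross-products;
    multiple linear regression of yield on component traits; genetic
    divergence grouping via Mahalanobis D2 with Tocher and hierarchical
    clustering; combined genotype-by-year ANOVA with sum-of-squares
    partitioning; and Geometric Adaptability Index (GAI) ranking and
    selection of superior genotypes. Includes a synthetic-data generator
    for balanced trials with known variance structure so every estimator
    can be validated against a recoverable truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
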