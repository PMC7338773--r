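Package: heatnorm
Title: Genomic Reaction Norms for Heat Tolerance in Sow Reproduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-step genomic reaction-norm analysis of heat tolerance in
    sow reproductive traits. Builds litter-specific weekly climate covariates
    (temperature, relative humidity and temperature-humidity index) from raw
    weather records, fits a random-regression reaction-norm model on
    first-order Legendre polynomials by Gibbs sampling with single-step GBLUP
    relationships (pedigree A, VanRaden method-2 G, blended H inverse) and
    five heterogeneous residual-variance classes, derives across-environment
    genetic correlation surfaces, environment-specific heritabilities and
    sire reaction norms, and performs a window-based single-step GWAS with
    back-solved marker effects, 10-SNP sliding windows and a circular
    bootstrap test. Includes a seeded synthetic-data generator emulating the
    full data structure (pedigree, genotypes, seasonal weather, repeated
    farrowing records) so every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    Matrix,
    coda,
    generics,
    stats,
    methods,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    readr,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Config/testthat/edition: 3
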