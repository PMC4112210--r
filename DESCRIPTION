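Package: blupscan
Title: Rapid Genome Scans by Linear Transformation of Genomic Breeding Values
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide association screening obtained as a by-product of a
    genomic evaluation. Breeding values predicted under a GBLUP animal model
    with a VanRaden genomic relationship matrix are linearly back-transformed
    to per-marker effect estimates, and each estimate is standardized by its
    own exact estimation variance (the SNP_ej statistic) or by its prediction
    error variance (SNP_epj). Candidate 2-Mb segments around per-chromosome
    peak markers are tested by partitioning the additive variance between a
    segment relationship matrix and its complement and comparing nested REML
    fits with a likelihood-ratio test referred to a chi-square with 0.5
    degrees of freedom. Includes a single-marker mixed-model (EMMA-style)
    scan for cross-checking, a plasmode permutation harness for empirical
    type-I-error evaluation, and a seeded F2-cross simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
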