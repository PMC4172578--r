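Package: supergwas
Title: SUPER Mixed-Model Genome-Wide Association Scans with
    Trait-Specific Complementary Kinship
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mixed linear model (MLM) genome-wide association scans with
    spectral REML variance-component estimation, P3D/EMMAX fixed-ratio
    marker tests, and the SUPER procedure: a preliminary scan, selection
    of pseudo-QTNs as bin representatives by restricted-likelihood
    optimisation over bin size and bin count, and per-marker tests under
    a complementary trait-specific kinship that excludes pseudo-QTNs in
    linkage disequilibrium with the tested marker. Includes VanRaden
    genomic kinship with exact marker-exclusion downdates, structured
    genotype and additive-phenotype simulators, and an empirical-null
    power and type-I-error evaluation driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
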