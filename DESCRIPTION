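Package: alidose
Title: Dosimetry and Assay Statistics for Air-Liquid-Interface Nanoparticle
    Exposure Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in vitro air-liquid-interface (ALI)
    aerosol exposure studies of nanoparticles: WST-1 plate-reader viability
    normalisation with blank correction and interference flagging,
    hierarchical Bayesian multi-plate consensus estimation with Half-Cauchy
    variance priors and a DerSimonian-Laird fallback combiner, SMPS
    number-size-distribution to mass-concentration conversion with
    size-cutoff policies and mode detection, ICP-MS blank correction with
    detection limits and compartment dose bookkeeping, deposition-efficiency
    dosimetry with in vivo dose-rate comparison and particle
    surface-coverage estimation, Shewhart-style assay control charting, and
    ToF-SIMS spectral statistics (unit-mass binning, peak-sum normalisation,
    PCA, Fisher discriminant with leave-one-out cross-validation, and
    per-ion group comparison). Includes seeded synthetic-data generators
    emulating the statistical structure of every input so the whole pipeline
    is testable without instrument data.
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
    readr,
    ggplot2,
    stats,
    generics
Suggests:
    testthat (>= 3.0.0),
    metafor,
    MASS,
    jsonlite,
    withr
Config/testthat/edition: 3
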