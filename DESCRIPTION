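Package: warmtrait
Title: Seasonal Warming Effects on Soil Microbial Traits and Heterotrophic Respiration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking experimental soil warming to microbial
    community traits and heterotrophic respiration on a monthly time scale.
    Implements community-aggregated rRNA operon (rrn) copy number traits with
    rank-fallback copy-number assignment, data-driven cool/warm season
    segmentation from a fifth-degree polynomial temperature fit, functional
    gene microarray quality control, normalization and response-ratio
    analysis, a microbial-enzyme decomposition (MEND-type) soil carbon model
    with temperature-dependent carbon use efficiency, multiobjective
    calibration by Shuffled Complex Evolution with Critical Objective
    Function Index uncertainty, a first-order (CENTURY/TECO-type) baseline
    model calibrated by Metropolis-Hastings MCMC, and carbon use efficiency
    temperature-sensitivity analytics. A seeded synthetic-data generator
    emulates the statistical structure of a paired warming field experiment
    so the full chain runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
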