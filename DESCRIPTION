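Package: phytotime
Title: Probabilistic Models for Phytoextraction Timeframes of Soil Contaminants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simplified probabilistic models for estimating how long
    phytoextraction needs to bring a contaminated soil down to a target
    concentration. Implements a linear steady-state extraction model and a
    first-order exponential decay model driven by two aggregated plant
    variables, the bioaccumulation factor (BAF) and the harvestable biomass
    production (BMP), with Monte Carlo propagation of their uncertainty
    (Beta-PERT and zero-truncated Normal input distributions), most-likely
    (mode) and 5th/95th-percentile summaries, Spearman rank sensitivity
    analysis, scenario engines (concentration-dependent efficiency gradient,
    BAF sweeps against a remediation deadline, optimised biomass), packaged
    field and literature parameter sets for DDT-contaminated soil, and a
    synthetic field-study generator for testing the distribution-fitting path.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
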