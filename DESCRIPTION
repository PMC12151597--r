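Package: weedbeetle
Title: Plant-Beetle Dynamics for Biocontrol of Tradescantia fluminensis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the initial stages of beetle biocontrol of the invasive
    ground-cover herb Tradescantia fluminensis. Provides a stochastic
    branching-plant simulator (nodes, leaves, tips, basal death), mean-field
    ODE models of plant, beetle and coupled plant-beetle dynamics with
    Holling type-II grazing, eigenvalue-based calibration of demographic
    rates from summary observations, critical-release-size experiments for
    three chrysomelid beetle species, and Monte Carlo sensitivity analysis
    with regression effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
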