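Package: fusevol
Title: Coevolution of Daughter-Cell Size and Binary Cell-Fusion Rate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and adaptive-dynamics analysis of the coevolution of
    daughter-cell mass and binary cell-fusion rate in unicellular populations.
    Provides a deterministic growth-cycle engine with mass-action fusion
    kinetics and mass-dependent survival, a stochastic mutation-selection
    simulator with fixed, scheduled, or telegraph-switching environments and
    plastic (environment-specific) genotypes, closed-form selection gradients
    with fixed-point, bifurcation, basin-of-attraction and separatrix analysis,
    and closed-form conditions for facultative (stress-induced) cell fusion in
    switching environments. Results are returned as tibbles, with ggplot2
    plotting helpers and broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
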