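Package: flowreactor
Title: Laminar Tube-Reactor Simulation and Factorial Screening for
    Continuous-Flow Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transient two-dimensional axisymmetric simulation of a laminar
    convection-diffusion-reaction tube reactor with Arrhenius second-order
    kinetics, aimed at continuous-flow synthesis of pharmaceutical
    intermediates (the enamine condensation of methyl 4-methoxyacetoacetate
    with DMF-DMA, the first step towards dolutegravir).  Includes ideal
    mixture property rules, analytic batch and residence-time-distribution
    reactor models used as solver cross-checks, two-level (fractional)
    factorial design generation with half-normal/Lenth effect screening and
    coded-unit log-yield regression, a seeded pseudo-experimental campaign
    generator with an impurity side channel and replicate noise, and parity
    analysis of predicted versus observed yields.
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
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
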