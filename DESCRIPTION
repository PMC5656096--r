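Package: agewave
Title: Hybrid Stochastic-Deterministic Simulation of Age-Structured
    Tumour Growth Waves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators and analysis tools for an oxygen-limited,
    age-structured birth-death-diffusion model of tumour cell invasion on a
    one-dimensional compartment lattice.  Provides an exact age-structured
    stochastic simulation algorithm, a coarse-grained (age-averaged)
    stochastic model, a coarse-grained mean-field reaction-diffusion model,
    and a hybrid scheme that couples the mean-field bulk to the fully
    stochastic front across a moving interface.  Includes the Euler-Lotka
    growth-rate and equilibrium age-distribution toolkit used for the
    coarse-graining, quasi-steady and dynamic oxygen solvers, travelling-wave
    front statistics, and birth-rate fluctuation diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
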