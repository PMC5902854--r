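Package: aedesfvm
Title: Finite-Volume Simulation of Aedes aegypti Population Dynamics in
    Urban Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the spread of Aedes aegypti mosquito populations
    through city neighbourhoods with a two-compartment
    reaction-advection-diffusion model: a winged (mobile) phase
    transported by wind and random flight, coupled to a static aquatic
    phase (eggs, larvae, pupae) through oviposition and maturation with
    logistic regulation.  The domain is a raster of rectangular city
    regions (building blocks, streets, parks, beach) carrying piecewise
    constant area-support, wind, diffusion and insecticide-kill
    coefficients.  The solver is a cell-centred finite volume scheme
    with first-order upwind advection, two-point central diffusion and
    forward-Euler time stepping under a CFL bound.  Ready-made scenario
    presets cover a generic city quarter, a Juiz de Fora city-centre
    neighbourhood with two adulticide deployment strategies, and the
    Copacabana beach front with periodic day/night winds; diagnostics
    integrate total populations over the domain and compare insecticide
    strategies as percentage reductions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
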