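Package: bqsim
Title: Consumer-Resource Simulation of Black Queen Dynamics in Soil Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates 20-species prokaryote communities in soil-aggregate
    environments with an ODE consumer-resource model. Species carry two
    public-good traits (cellulase and amino-acid production) crossed with two
    life strategies (copiotroph, oligotroph), pay trait-dependent maintenance
    burdens, and can lose functions by stochastic mutation. A Monte Carlo
    scenario driver runs replicate communities across bulk-soil (pulsed
    cellulose) and rhizosphere (continuous glucose) feeding regimes, and
    summary statistics relate Shannon diversity, functional-group composition
    and life strategy to cumulative biomass production, including
    Tragedy-of-the-Commons outcomes under rising mutation rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
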