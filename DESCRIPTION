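Package: fisherygame
Title: Evolutionary Game Dynamics of Cooperation in Effort-Restricted
    Small-Scale Fisheries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models whether compliance with a fishing-effort restriction can
    persist in a small-scale fishery. Builds penalized 2x2 payoff matrices
    for cooperator and cheater fisher populations from a Gordon-style
    bioeconomic harvest model, applies a behaviour penalty combining control
    perception and risk tolerance with stock growth rate, classifies the
    resulting evolutionary game (dominance, coexistence, bistability, no
    fishing), integrates replicator dynamics on the cooperator-frequency
    simplex, and sweeps stock growth rate against relative stock size to map
    outcome phase diagrams. Ships the parameterization of a
    restricted-effort shrimp fyke-net fishery in Laguna, southern Brazil.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
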