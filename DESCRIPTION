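Package: scenepd
Title: Self-Confirming Equilibria and Observational Learning in the Noisy
    Iterated Prisoner's Dilemma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact analysis of the iterated Prisoner's Dilemma among the sixteen
    memory-one pure strategies when moves are misimplemented with a small error
    probability. Computes stationary distributions and long-run payoffs of the
    two-player Markov chain as exact rational functions of the error rate,
    enumerates best responses in the small-error limit, recovers the critical
    cooperation-cost thresholds at which best responses switch, and models a
    Bayesian observer who must infer the resident strategy from a limited number
    of observed interactions. Classifies strategies as Nash equilibria,
    self-confirming equilibria (SCE), and both at once (SCENE), and maps how the
    observer's prior over candidate strategies determines the best-looking
    response across the probability simplex. Includes seeded Monte-Carlo
    generators for match trajectories and observational samples so every
    analytic result has a simulation oracle.
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
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
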