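Package: altdrift
Title: Fixation of Altruistic Alleles in Populations with Variable Carrying Capacity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the competition between an altruistic allele
    that enlarges the carrying capacity of its habitat and a selfish allele of
    higher fitness, in a birth-death generalization of the Moran model where
    total population size fluctuates between two bounds. Provides exact
    fixation probabilities from a sparse backward Kolmogorov solve over the
    trapezoidal state space, Monte-Carlo estimates from a Gillespie jump-chain
    simulator, closed-form and first-order diffusion approximations (including
    the Kimura formula and the selection criterion for altruist advantage),
    the low-migration stepping-stone extension for geographically structured
    populations, deterministic mean-field dynamics, and scripted parameter
    sweeps with a command-line front end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
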