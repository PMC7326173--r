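Package: greengame
Title: Stochastic Evolutionary Games of Green Technology Innovation in
    Finite Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A frequency-dependent Moran-process engine for two-stage
    evolutionary games of green technology innovation in finite populations.
    Builds economic payoff matrices (innovate vs. free-ride, lead vs. follow)
    from discounted market rewards and policy incentives, computes exact
    fixation probabilities of invading strategies by the birth-death product
    formula with an independent absorbing-chain oracle, provides first-order
    weak-selection approximations, Monte Carlo simulation of the process with
    mutation, and parameter sweeps that locate incentive thresholds and
    incentive-inequality trade-offs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
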