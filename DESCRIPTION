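Package: sbtip
Title: Schrodinger Bridge Transition Paths and Tipping Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes transition-path measures between two meta-stable invariant
    sets of a stochastic dynamical system by likelihood training of the
    Schrodinger-bridge forward-backward stochastic differential equation system,
    and derives an action-functional (Benamou-Brenier kinetic energy) early-warning
    indicator on the resulting flow of probability measures. Includes a
    Morris-Lecar neuron simulator with invariant-set extraction, semi-discrete
    optimal transport (discrete Brenier potential) for non-convex targets,
    closed-form Gaussian bridge oracles, seeded synthetic-data generators, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
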