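Package: neurobo
Title: Bayesian Optimization of Neuromodulation Parameters with Boundary
    Avoidance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for studying Bayesian optimization of
    neurostimulation parameters (amplitude and pulse width) under the low
    effect sizes typical of neurological and psychiatric outcomes.
    Generates synthetic patient-response surfaces with quadratic safety
    boundaries and calibrated Cohen's d, runs Gaussian-process-based
    optimization protocols with five acquisition functions (maximum
    variance, UCB, GIBBON-style max-value entropy search, epsilon-greedy
    Pareto, and a GIBBON/Pareto mixture), quantifies the boundary
    over-sampling failure mode via boundary variance ratios, and
    implements the mitigation: an iterated Brownian-bridge kernel whose
    covariance vanishes on the domain boundary combined with an input
    warp that maps the safety boundary onto the edges of the parameter
    box.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
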