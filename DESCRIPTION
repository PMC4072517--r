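Package: chemodrift
Title: Run-and-Tumble Chemotaxis Simulation and Drift-Velocity Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic single-cell simulation and analytical theory of
    bacterial chemotaxis in exponential attractant gradients. Implements a
    Monod-Wyman-Changeux receptor-cluster module with methylation (integral
    feedback) adaptation, an ultrasensitive two-state flagellar motor with
    optional slow FliM-ring adaptation, a three-dimensional run-and-tumble
    agent-based simulator, and the matching linearized drift-velocity theory
    with behavioral feedback: fixed points, bifurcation (chemotactic trap)
    analysis, optimal phenotypes, and performance trade-off maps across
    gradient length scales.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
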