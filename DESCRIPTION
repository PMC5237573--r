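Package: dombayes
Title: Bayesian Dominance Models for Simulated Quantitative-Trait GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico workbench for genome-wide association analysis with
    additive and dominance effects. Provides a forward Wright-Fisher
    simulator of a one-Morgan chromosome with a declining effective
    population size, a quantitative-trait generator with a realistic joint
    distribution of additive effects and dominance coefficients, Gibbs
    samplers for the BayesC (additive) and BayesD (additive plus dominance)
    mixture-prior multi-marker models, sliding-window posterior probability
    of association (WPPA) inference, and power / precision evaluation of
    QTL mapping across marker densities, window sizes and decision
    thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
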