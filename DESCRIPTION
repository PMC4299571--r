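Package: mnhcea
Title: Bayesian Cost-Effectiveness and Affordability Analysis of Maternal
    and Newborn Health Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for trial-based Bayesian cost-effectiveness analysis of
    maternal and newborn health interventions evaluated in cluster-randomised
    trials. Provides a cost model (joint-cost allocation, capital
    annualisation, currency conversion to international dollars), a
    synthetic-data generator for 2x2 factorial cluster trials with binomial
    mortality counts, Bayesian logistic effect models fitted by an adaptive
    Metropolis-within-Gibbs sampler, conversion of posterior odds ratios to
    deaths and DALYs averted, probabilistic decision analysis (ICER, expected
    incremental benefit, cost-effectiveness acceptability curves, expected
    value of perfect information), and deterministic national scale-up and
    affordability modelling with differential discounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
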