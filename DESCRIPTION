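Package: todesign
Title: Triple-Outcome Double-Criterion Optimal Design for Two-Dose
    Randomized Trials
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Design and calibration of Bayesian two-stage, two-dose
    randomized dose-monitoring-and-optimization trials.  A dynamic linear
    model with a probit link and half-Cauchy borrowing prior links the
    dose-specific response rates; per-dose futility monitoring and a
    triple-outcome (select higher dose / select lower dose / inconclusive)
    noninferiority comparison drive the trial decision.  Provides a
    deterministic quadrature posterior engine with a seeded MCMC
    cross-check, exact enumeration and Monte Carlo operating
    characteristics, a two-step grid-search calibration of sample sizes
    and posterior-probability cutoffs, beta-binomial comparator designs
    (including Simon's optimal two-stage design), and a utility-based
    extension for joint toxicity-efficacy dose optimization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
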