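Package: condesign
Title: Simulation-Based Design Optimization for Classical Conditioning Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating and optimizing the design of classical
    (Pavlovian) conditioning experiments by simulation. Experiments are
    formalized as trial-generating Markov chains with stage-wise or periodic
    contingency parameterizations; conditioned responses are simulated from a
    space of associative-learning models (Rescorla-Wagner, Kalman
    Rescorla-Wagner, and Rescorla-Wagner/Pearce-Hall hybrids with three
    response mappings); simulated datasets are analysed by maximum-likelihood
    estimation and BIC model selection; and designs are scored by Monte-Carlo
    expected utility (negative parameter-estimation error or model-selection
    accuracy) and tuned by Gaussian-process Bayesian optimization. Includes
    design-comparison statistics (common-language effect sizes with bootstrap
    intervals, odds ratios with Woolf/Haldane-Anscombe intervals, exact
    Clopper-Pearson binomial intervals, confusion matrices) and a library of
    reference designs (acquisition-extinction, backward blocking, reversal
    learning) with end-to-end scenario runners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
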