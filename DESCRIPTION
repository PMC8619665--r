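Package: esgfam
Title: Exponentiated Sine-Generated Distribution Families for Lifetime Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the exponentiated sine-generated (ESG) family of
    lifetime distributions and its Weibull-based member, the exponentiated
    sine-Weibull (ESW) distribution. Provides distribution, density,
    quantile and random-generation functions over pluggable baselines,
    truncated power-series expansions of the density, moments and Renyi
    entropy, maximum-likelihood fitting with observed-information Wald
    intervals and goodness-of-fit statistics, Bayesian estimation under
    independent gamma priors by Metropolis-Hastings within Gibbs with
    highest-posterior-density intervals, stress-strength reliability
    P(Y < X) for two populations sharing a scale parameter with
    nonparametric bootstrap confidence intervals, and Monte-Carlo
    simulation harnesses for estimator performance studies. Fitted objects
    follow broom conventions (tidy(), glance()) and results plot with
    ggplot2.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    patchwork,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
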