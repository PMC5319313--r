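Package: bayesrep
Title: Bayesian Reassessment of Replication Studies from Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Default Bayesian reanalysis of replication studies from summary
    statistics. Provides Jeffreys-Zellner-Siow (JZS) Bayes factors for one-
    and two-sample t-tests with two-sided and directional (folded) Cauchy
    priors, effect-size posteriors for the standardized mean difference and
    the proportion of variance explained, prior-width robustness curves,
    posterior inference for Pearson correlations under stretched-beta priors
    and for Cramer's phi-squared from contingency tables, and a Bayesian
    random-effects meta-analysis of standardized effect sizes with shrinkage
    reporting. Includes a calibrated synthetic study-set generator and a
    batch pipeline that classifies evidence into Jeffreys categories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
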