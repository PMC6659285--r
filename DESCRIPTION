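Package: perceptPA
Title: Streetscape Perception Scoring and Multilevel Models of Physical Activity
Version: 0.1.0
Authors@R:
    person("perceptPA", "Maintainers", email = "maintainers@perceptpa.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline from street-scene composition to
    physical-activity inference. Provides a synthetic-world generator
    (Dirichlet scene compositions with neighbourhood structure, a noisy
    volunteer-rater oracle, and a two-level survey with IPAQ-style activity
    items), a human-machine adversarial perception-scoring system built on a
    bagged regression-tree ensemble with a rolling-RMSE convergence rule,
    circular-buffer aggregation of image scores to neighbourhood exposures,
    a self-contained random-intercept linear mixed model (profiled ML/REML)
    with ICC, VIF and Wald inference, and an orchestration layer reproducing
    a seven-model analysis suite with parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
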