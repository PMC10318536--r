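Package: bbsms
Title: Rasch-Based Psychometric Validation of the Berg Balance Scale in
    Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("BBS-MS", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for the psychometric validation of the
    14-item Berg Balance Scale (BBS) in persons with Multiple Sclerosis.
    Implements classical item analysis, Mokken scalability with automated
    item selection, ordinal confirmatory factor analysis on polychoric
    correlations, partial credit Rasch analysis estimated by conditional
    maximum likelihood, local-dependence diagnostics with a relative
    cut-off, testlet adjustment, differential item functioning with
    split-impact assessment, anchored cross-sample confirmation,
    distribution-independent reliability strata, raw-score-to-measure
    conversion, and external construct validity with non-parametric
    effect-size conversions.  A synthetic-data generator reproduces the
    statistical structure of a mistargeted multi-centre clinical sample so
    that the whole pipeline is exercisable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
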