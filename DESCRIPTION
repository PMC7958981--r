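Package: crowdtrust
Title: Trustworthiness and Reliability Metrics for Crowdsourced Video Raters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring the trustworthiness and reliability of crowd
    workers who tag behavioral features in short videos for autism versus
    neurotypical classification. Implements four per-worker behavioral
    metrics (mean same-child L1 distance, mean pairwise internal L1
    distance, penalized time, and mean rating time), probability-of-correct-
    class (PCC) scoring through a configurable logistic-regression
    classifier, Pearson correlation screening with Bonferroni correction, a
    sweep over the penalized-time weighting constant, exhaustive
    metric-subset linear regression with worker-level k-fold cross-validated
    mean absolute error, and cross-cohort generalization error. A synthetic
    cohort generator emulates workers of varying diligence (including
    copy-paste answering, minimum-time warnings with revisions, and a
    delayed re-rating of the same videos) so the whole pipeline is testable
    and its parameter-recovery behavior can be verified without access to
    any real worker data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
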