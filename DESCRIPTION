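Package: metacrowd
Title: Confidence-Weighted Crowdsourcing with Metacognition-Based User Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying whether recording graded confidence judgments
    improves two-choice crowdsourcing. Implements an equal-variance
    signal-detection model of Type I choices and Type II confidence, Type II
    ROC / AUROC2 metacognitive sensitivity scoring, majority-vote and
    confidence-weighted majority-vote answer aggregation with exact
    (Poisson-binomial) and closed-form normal-approximation expected errors,
    Monte-Carlo population sweeps over performance and metacognition filter
    grids, a resampling evaluation pipeline for trial-level behavioral data,
    and a synthetic-cohort generator emulating a word-recognition memory task
    and a tweet author-gender task.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
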