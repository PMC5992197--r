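Package: ensemblerecall
Title: Reinforcement-Gated Ensemble Recall Analysis for Maze Inter-Trial Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for neural ensemble co-activity during the
    self-paced inter-trial intervals of Y-maze rule-learning sessions.
    Provides spike-density similarity matrices, interval-by-interval recall
    matrices with an inter-spike-interval shuffle null to correct for
    duration bias, outcome/arm/cue block comparisons with
    Kolmogorov-Smirnov tests, change-point detection of recall onset and
    offset, behavioural learning-trial identification via robust
    piecewise regression, position-dependent cross-validated decoding of
    retrospective and prospective task features with shuffled-label chance,
    and a synthetic session generator with ground-truth labels for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
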