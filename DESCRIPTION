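Package: dazzletrack
Title: Simulation and Mixed-Model Analysis of Motion Dazzle Tracking Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating and analysing target-tracking experiments on
    motion dazzle camouflage and the confusion effect.  Renders striped and
    binary-noise square stimuli at controlled luminance contrast, simulates
    confined correlated random walks of groups of moving squares, generates
    synthetic observer tracking data exhibiting the confusion effect, computes
    tracking-error statistics, and fits maximum-likelihood random-intercept
    linear mixed models with a ladder of likelihood-ratio tests, Tukey-type
    post hoc contrasts and within-subject confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    mvtnorm,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    multcomp,
    optparse,
    jsonlite,
    withr,
    png
Config/testthat/edition: 3
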