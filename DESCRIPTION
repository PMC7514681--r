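Package: nirsmse
Title: Multiscale Entropy Analysis of Prefrontal fNIRS Recordings
Version: 0.1.0
Authors@R:
    person("nirsmse", "developers", email = "nirsmse@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for complexity analysis of prefrontal
    functional near-infrared spectroscopy (fNIRS) recordings acquired under
    different communication media. Implements preprocessing (first-order
    Butterworth bandpass, linear detrending, rest-period eigen-decomposition
    removal of the superficial skin-blood-flow component), coarse-grained
    multiscale sample entropy (MSE), nonparametric repeated-measures group
    statistics with effect sizes (Friedman, paired Wilcoxon signed-rank,
    Spearman, Bonferroni), and an MSE-threshold classifier of self-reported
    fatigue with confusion-matrix metrics. A seedable synthetic-cohort
    generator with planted spectral complexity, systemic physiological
    artifacts, a low-rank shared skin-blood-flow component and a planted
    fatigue link makes every stage testable without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
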