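Package: stridemet
Title: Within-Stride Metabolic Rate Time Profile Estimation from Gait Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the time profile of metabolic rate within the walking
    stride cycle from joint-level gait data. Implements an EMG-driven
    Hill-type muscle-tendon simulation with muscle metabolic energetics
    (activation-maintenance heat, shortening-lengthening heat, and fiber
    mechanical work), and a joint-space estimator driven by joint moments
    and angular velocities. Includes per-participant calibration of tendon
    slack length and optimal fiber length by generalized pattern search
    against reference joint moments, gait-cycle phase partitioning, a
    synthetic gait-trial generator for method evaluation, and
    repeated-measures correlation statistics for method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
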