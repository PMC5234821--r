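Package: occlusioncf
Title: Occluded Car-Following Simulation and Task-Difficulty Homeostasis Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates self-paced visual-occlusion car-following experiments, in
    which a follower's view is masked except for brief self-requested glances,
    and implements the analysis pipeline used to test task-difficulty
    homeostasis in car-following models: geometric-mean time-headway and
    occlusion-duration aggregates, Spearman correlation comparison of
    baseline-independent versus baseline-relative headway adaptation (with
    Fisher-z and Zou difference confidence intervals), robust Theil-Sen
    detrending of glance-onset series, exact binomial sign tests, and
    per-subject Passing-Bablok symmetric regression.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
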