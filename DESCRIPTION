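Package: napscope
Title: Joint-Angle Movement Analysis for Video-Based Sleep Posture Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts streams of 12 named 2D body-pose landmarks into
    joint-angle time series, derives per-session movement indices
    (number of posture changes, maximum change, stable times), and runs a
    nonparametric repeated-measures comparison across exposure conditions
    (Friedman tests with Kendall's W, Wilcoxon signed-rank post hocs with
    effect size r, Spearman correlations, Bonferroni correction). A
    synthetic nap-session simulator with known ground truth makes the full
    pipeline testable without video input.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
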