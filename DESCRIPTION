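Package: enmocut
Title: Raw-Acceleration Cut Points for Children's Sedentary and
    Stationary Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calibration and validation of raw-acceleration (ENMO,
    Euclidean norm minus one) cut points that classify sedentary and
    stationary behaviour in children from wrist- and hip-worn
    accelerometers, against a thigh-worn posture logger as criterion.
    Reduces 100 Hz tri-axial signals to 1 s ENMO epochs, expands posture
    event logs to second-by-second labels with the transitioned-into rule
    for duplicate seconds, derives Youden-optimal thresholds from ROC
    curves with DeLong confidence intervals, and computes the free-living
    agreement battery (paired t, Cohen's d, Bland-Altman limits of
    agreement, Pearson r, MPE/MAPE, 10-percent-zone equivalence testing).
    Includes a synthetic-data generator for a seven-station calibration
    protocol plus recess and for semi-Markov free-living days, so the
    whole pipeline runs with no external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
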