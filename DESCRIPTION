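Package: windupr
Title: Quantification of Pain Wind-Up from Calcium Imaging,
    Spinal Electrophysiology and Human Psychophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for temporal summation ("wind-up") of
    nociceptive signalling across preparations: repeat-reliability
    quality control and decay-kinetics (tau) extraction for in vitro
    Fura-2 ratio traces, delta-F/F normalisation and stimulus-evoked
    response detection for in vivo calcium recordings, spike-train
    wind-up statistics (latency banding, input/wind-up decomposition,
    one-phase association rate constants) for dorsal horn unit
    recordings, the human wind-up ratio with its quality-control
    rules, Dixon up-down withdrawal thresholds, Box-Cox normality
    tuning by the Lilliefors statistic, and analytic plus simulated
    power for single-SNP association tests. A synthetic-data module
    generates all input classes with known ground truth so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    withr,
    pracma
Suggests:
    testthat (>= 3.0.0),
    nortest,
    car
Config/testthat/edition: 3
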