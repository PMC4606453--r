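Package: larvasleep
Title: Sleep, Arousal-Threshold and Stimulus-Response Analysis for Larval
    Zebrafish Behavioral Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing videotracker recordings of larval zebrafish
    behavior: sleep/wake scoring from minute-binned locomotor activity
    (sleep, waking activity, bout structure, latency), heat-shock
    sleep-change ratios, an arousal-threshold tap assay with
    background-corrected response fractions, variable-slope log(dose)
    response curve fitting with ETP50 estimation and nested-model
    comparison by the extra sum-of-squares F test, optogenetic
    light-response analysis on 10-s-binned activity, and stimulus-locked
    GCaMP delta-F/F quantification. Includes synthetic-data generators
    that emulate each assay so every pipeline stage can be exercised and
    validated by parameter recovery without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    minpack.lm,
    optparse
Config/testthat/edition: 3
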