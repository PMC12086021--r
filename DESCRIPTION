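Package: oddball
Title: Deviance-Detection Analysis for Auditory Oddball Spike-Train Recordings
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for trial-based extracellular recordings from
    auditory cortex under an oddball (deviance-detection) paradigm with
    within-session drug conditions. Provides a session data model and
    trial-aligned firing-rate extraction into SummarizedExperiment
    containers, neuron inclusion filters (firing-rate stability,
    signed-rank responsiveness with Bonferroni correction, evoked-rate
    floor, locomotion-state classification), Gaussian frequency-tuning
    fits on log-spaced tone ensembles, oddball enhancement and
    drug-modulation indices with paired nonparametric population tests,
    Fano-factor variability analyses split by locomotion state, an
    adaptation control and a matched-resampling control, and a seeded
    synthetic spike-train generator that emulates the paradigm structure
    (tuning blocks, role-swapped chord and FM oddball blocks, three
    within-session periods) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
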