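Package: pupilci
Title: Pupillometric Listening-Effort Analysis for Cochlear-Implant Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline linking speech-in-noise task
    difficulty (signal-to-noise ratio) to pupillometric listening effort in
    cochlear-implant users. Provides trial-level pupil-trace cleaning
    (median-absolute-deviation artifact detection, margin expansion, cubic
    interpolation, smoothing, exclusion), baseline normalization and
    peak-pupil-dilation (PPD) extraction; mixed-effects psychometric models of
    PPD, intelligibility and subjective workload against SNR with polynomial
    shape analysis; scoring of an individual-differences battery (adaptive
    spectral-ripple staircase, N-back d-prime, Stroop, NASA-TLX, NCIQ); and a
    Pearson/Spearman correlation battery with Bonferroni correction. A
    synthetic-cohort generator with participant-specific inverted-U effort
    curves provides ground truth for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    multcomp,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
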