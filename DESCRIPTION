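Package: mfphnr
Title: Multifocal Photopic Negative Response Simulation and Topographic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the multifocal photopic negative response (mfPhNR)
    paradigm of visual electrophysiology: construction of the 60-segment
    scaled dartboard stimulus geometry with ring, quadrant-sector and
    ETDRS-style retinal topographies; maximum-length (m-)sequence stimulation
    schedules and first-order kernel extraction by cross-correlation;
    baseline-to-trough response amplitude density (RAD) measurement;
    a seeded synthetic-cohort generator calibrated to published group
    summaries of control and multiple-sclerosis optic-neuritis eyes; and a
    statistics layer (one-way ANOVA from raw values or printed summaries,
    eccentricity-decay fits, Kolmogorov-Smirnov normality, noncentral-t
    power/sample-size) that reproduces the reference study's printed tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
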