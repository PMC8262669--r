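Package: emaflow
Title: Ecological Momentary Assessment Workflow Engine with Tapping-Test Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless engine for home-based ecological momentary assessment
    (EMA) studies in Parkinson disease: versioned study protocols with
    subjective scales and a daily sleep diary, anchor-driven session
    scheduling with expiry, scoring of 30-second alternating two-key
    finger-tapping trials (kinesia, akinesia, incoordination, dysmetria),
    touchscreen target-ratio usability analytics, store-and-forward
    persistence with filtered CSV export, compliance and satisfaction
    analytics, and a synthetic patient-behavior simulator with known ground
    truth so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
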