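Package: thyrowear
Title: Wearable Resting Heart Rate as a Digital Marker of Thyroid Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts resting heart rate from intraday wearable
    heart-rate and step logs by an activity-gated window algorithm (daily
    median over activity-free minutes, averaged over the five days before
    each clinic visit), scores thyrotoxicosis clinical status
    (Hyperthyroidism Symptom Scale totals, thyroid-status labels, the
    binary free-T4 outcome), and quantifies the association between
    resting heart rate and thyroid function with standardized linear and
    binary logistic generalized estimating equations using cluster-robust
    sandwich variance. Includes a calibrated longitudinal synthetic-cohort
    generator (free-T4 treatment trajectories, circadian and
    activity-driven heart-rate structure, device non-wear) so the full
    pipeline is testable end to end, plus descriptive two-group and
    repeated-measures tests and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    tibble,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
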