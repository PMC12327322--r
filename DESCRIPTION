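Package: drynights
Title: Early Prediction of Enuresis Alarm Treatment Outcome from Nightly Diaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the outcome of enuresis (bedwetting) alarm
    treatment from patient diary calendars while treatment is still running.
    The package simulates cohorts of treatment calendars, engineers
    registration, nightly and rolling-window features with explicit
    missing-data compensation, assigns ICCS-style response labels
    (successful, partially successful, unsuccessful, dropout), trains one
    random-forest classifier per treatment day with SMOTE class balancing and
    cross-validated grid search, and evaluates daily predictions including
    optimization of decision thresholds by a true-positive to false-positive
    quotient.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    jsonlite,
    yaml,
    ranger,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
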