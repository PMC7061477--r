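Package: tariffva
Title: Tariff-Based Verbal Autopsy Cause-of-Death Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for producing cause-of-death statistics from verbal
    autopsy (VA) interviews in civil registration and vital statistics
    settings. Trains tariff scores (median/IQR-standardised symptom
    endorsement rates) from a gold-standard database, assigns each death a
    cause or an undetermined label by ranking against a uniformly resampled
    baseline, redistributes undetermined deaths using gold-standard
    undetermined-propensity weights averaged with reference age-sex cause
    fractions, estimates cause-specific mortality fractions (CSMFs) with
    percentile-bootstrap confidence intervals, and assesses plausibility
    against a reference age and broad-cause distribution. Includes a
    synthetic-data generator so every stage is testable without restricted
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
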