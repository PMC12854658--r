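Package: bleedr
Title: Detection of Antithrombotic-Related Bleeding in Inpatient EHR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computable-phenotype engine for detecting major bleeding (MB) and
    clinically relevant nonmajor bleeding (CRNMB) among older inpatients treated
    with antithrombotic agents. Implements a rule-based detector over structured
    electronic health record data (hemoglobin time series, transfusions,
    antihemorrhagic prescriptions, ICD-10-GM diagnosis codes), a three-stage
    supervised sentence classifier for discharge summaries with priority-based
    document aggregation, union/intersection combination of detectors, and a
    validation toolkit (sensitivity, specificity, predictive values, accuracy,
    F1, Wilson score intervals, Fleiss kappa). A seeded synthetic cohort
    generator emits structured tables and template discharge summaries with
    ground-truth labels so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    jsonlite,
    glmnet,
    e1071,
    Matrix,
    withr,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
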