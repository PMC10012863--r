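Package: planreviewr
Title: Bayesian-Network Assisted Initial Review of Radiotherapy Treatment Plans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probabilistic quality assurance of external-beam
    radiotherapy treatment plans. Learns a discrete Bayesian network over
    diagnostic, patient-setup, treatment-planning and dose-prescription
    variables from tabular plan records (EM with Laplace smoothing, exact
    inference by variable elimination), scores each plan variable by its
    conditional marginal probability under configurable evidence strategies,
    and flags improbable values as potential errors. Includes a synthetic
    multi-clinic cohort generator, a failure-mode error injector for the
    classic setup/planning/prescription categories, and an ROC/AUC evaluation
    harness for single-site, cross-site and pooled training designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
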