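Package: comorbmap
Title: Temporal Comorbidity Mapping for Dementia Subtypes from ICD-10
    Inpatient Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds temporal comorbidity profiles for Alzheimer's disease and
    vascular dementia from longitudinal first-instance ICD-10 inpatient
    records. Resolves an overall dementia diagnosis per participant from
    subtype code counts, matches age- and sex-matched controls with
    placeholder index dates, maps every comorbidity into pre- and
    post-diagnosis time windows, and identifies time- and subtype-specific
    characteristic conditions via Mann-Whitney prevalence tests with
    Bonferroni correction, per-window co-occurrence networks with degree
    centrality, per-window logistic regression with odds ratios and AUROC,
    and Cox time-to-death models. Includes a synthetic electronic-health-
    record generator with age-dependent baseline incidence and
    window-specific planted enrichment for end-to-end validation, plus a
    hip-fracture control-disease cohort for specificity checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
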