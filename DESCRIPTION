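Package: pvdiss
Title: Pharmacovigilance Signal Detection for Drug-Induced Sweet's Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for spontaneous-report pharmacovigilance
    analysis of drug-induced Sweet's syndrome (acute febrile neutrophilic
    dermatosis): reading FAERS-style quarterly ASCII extracts, case-level
    deduplication by FDA receipt date, case and primary-suspect drug
    definition, reporting odds ratio (ROR) disproportionality screening with
    Fisher exact tests and false discovery rate control, LASSO-refined
    multivariable logistic modelling across predefined indication-exclusion
    datasets, Weibull time-to-onset modelling, drug co-occurrence networks,
    and cross-database consistency assessment. Ships a synthetic FAERS-shaped
    report generator with planted signals so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    pROC,
    fitdistrplus,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
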