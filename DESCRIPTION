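Package: pancrisk
Title: Absolute Risk Modelling for Pancreatic Cancer from Pooled
    Case-Control Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits a multivariable logistic relative-risk model for
    pancreatic cancer from pooled cohort and case-control data
    (smoking, diabetes, family history, heavy alcohol use, body mass
    index, ABO genotype and three GWAS risk variants, with
    missing-indicator coding and design-stratified diabetes effects),
    calibrates the model to population incidence rates to produce
    age-specific, ten-year and lifetime absolute risks under competing
    mortality, and evaluates discrimination and reclassification
    (Mann-Whitney AUROC, DeLong paired comparison, net reclassification
    improvement). Includes winner's-curse adjustment of GWAS-derived
    per-allele estimates by conditional maximum likelihood, and a
    synthetic-data module that emulates the covariate and genotype
    structure of the pooled consortium data so the whole pipeline is
    testable without access to individual-level study data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
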