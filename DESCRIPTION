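Package: wburden
Title: Gene-Wise Weighted Burden Tests for Rare Variants in Case-Control
    Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Weighted burden analysis of rare functional variants in
    exome-sequenced case-control cohorts. Each variant receives a weight
    combining functional severity (VEP consequence with PolyPhen/SIFT
    modifiers) and rarity (linear in minor allele frequency on [0, 0.01]);
    per-subject gene-wise burden scores are tested by logistic-regression
    likelihood-ratio tests with ancestry principal components and sex as
    covariates, summarized as signed log10 P values (SLP). Includes variant
    QC filters, missing-genotype imputation, X-chromosome hemizygote
    handling, Fisher's-method gene-set analysis over GMT files, QQ-based
    calibration diagnostics, variant-category effect decomposition,
    derivation of heavy-drinking and problem-drinking phenotypes from
    questionnaire fields, and a synthetic stratified-cohort generator for
    end-to-end testing without access to biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    vcfR
Config/testthat/edition: 3
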