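Package: prsband
Title: Polygenic and Phenotypic Breast-Cancer Risk Models with Decile-Band Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates combined genotype-plus-phenotype breast-cancer
    risk models in a case-control design: SNP-panel filtering and call-rate QC,
    polygenic risk scores (PRS) with control-median normalization and
    control-SD standardization, genotype principal components, odds-ratio
    encoding of categorical risk factors, univariable and multivariable
    logistic models with age interactions, likelihood-ratio interaction tests,
    Hosmer-Lemeshow calibration, cross-validated AUC over repeated 90/10
    splits, and risk stratification into decile bands with odds ratios against
    the 40-60% reference band. Includes a synthetic case-control cohort
    generator (Hardy-Weinberg genotypes, logistic disease model, retrospective
    ascertainment) so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
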