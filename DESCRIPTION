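Package: fhscreen
Title: Familial Hypercholesterolemia Screening from Biobank Genotypes and Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for population screening of familial
    hypercholesterolemia (FH) from cohort genotypes and phenotypes.
    Provides variant- and sample-level quality control for a rare-variant
    gene panel, back-correction of LDL cholesterol for lipid-lowering
    medication, aggregation of ClinVar/HGMD/LOVD pathogenicity assertions,
    carrier penetrance statistics, Dutch Lipid Clinic Network (DLCN)
    scoring with and without genetic evidence, prevalence estimation,
    and gene-collapsed carrier burden tests with Firth-penalized logistic
    regression. A synthetic-cohort generator reproduces the statistical
    structure of a deeply phenotyped biobank so every stage can be tested
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
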