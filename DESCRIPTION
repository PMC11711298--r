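Package: gwasGP
Title: GWAS-Informed Genomic Prediction Benchmarking for Structured Crop Panels
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmarking pipeline for genomic prediction of agronomic traits
    in structured germplasm panels. From a biallelic SNP genotype matrix and
    multi-environment phenotype trials it computes mixed-model BLUP corrected
    phenotypes, population-genetic summaries (VanRaden kinship, PCA,
    Weir-Cockerham Fst, LD thinning), REML SNP heritability on a
    frequency-weighted thinned kinship, a P3D mixed-linear-model GWAS marker
    ranking, and compares seven prediction models (GBLUP, ridge, lasso,
    elastic net, kernel ridge regression, linear and polynomial support
    vector regression) under repeated five-fold cross-validation with nested
    hyperparameter tuning, using all markers or top-N GWAS-derived marker
    subsets. A synthetic-data module generates structured panels with known
    truth (QTL effects, heritability, Fst) so every stage is testable at desk
    scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    lme4,
    kernlab,
    vcfR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
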