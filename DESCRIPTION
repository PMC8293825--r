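Package: snplasso
Title: Standard and Robust Huber-LASSO for SNP-Based Prediction of
    Molecular Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Penalized regression of molecular phenotypes (protein,
    metabolite or expression residuals) on individual SNP dosages with
    least-squares, Huber and quantile loss functions. Provides an
    L1-penalized iteratively reweighted coordinate-descent solver with
    cross-validated penalty selection, eigenstrat-style genotype
    principal component analysis with exact trivariate halfspace
    (Tukey) depth for leverage diagnosis, outlier-injection simulation
    protocols, robust evaluation statistics (Jaccard concordance,
    false- and true-positive rates, Fisher-consistent rank
    correlations, empirical confidence intervals), and a seeded
    synthetic genotype/phenotype generator emulating the additive
    architecture of a typical plasma protein.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    VariantAnnotation,
    knitr
Config/testthat/edition: 3
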