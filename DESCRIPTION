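Package: gebvcv
Title: Relationship-Constrained Cross-Validation for Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how additive-genetic relationships between
    training and validation animals inflate the accuracy of genomic
    estimated breeding values (GEBVs), and to isolate the persistent
    accuracy component due to linkage disequilibrium.  Implements BayesB
    (Bayesian variable-selection regression via MCMC), G-BLUP on the
    genomic relationship matrix and pedigree BLUP on the numerator
    relationship matrix, all with reliability-weighted residuals; a
    cross-validation sampler that caps the maximum pedigree relationship
    (a_max) between training and validation bulls; an accuracy estimator
    for daughter-yield-deviation phenotypes; and the regression that
    decomposes GEBV accuracy into a relationship component and an
    LD component.  A synthetic-data module simulates multi-generation
    half-sib pedigrees, LD-bearing SNP haplotypes, gene dropping, QTL
    architectures and daughter yield deviations so the whole pipeline is
    testable without proprietary data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    withr,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
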