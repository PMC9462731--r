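Package: cfmr
Title: Cross-Fitted Instruments for One-Sample Mendelian Randomization
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Conservative one-sample Mendelian randomization through
    cross-fitted instruments (CFI). The exposure is predicted, for each fold
    of a random partition, by a genetic predictor trained on the fold's
    complement (per-fold GWAS, greedy clumping, p-value selection and
    L1-penalized regression); the concatenated out-of-fold predictions serve
    as the instrument in two-stage least squares. Includes the CFMR1
    (fold-averaged) and CFMR2 (pooled-instrument) estimators, the naive
    one-sample MR baseline, a Nagar endogeneity-bias diagnostic, per-stratum
    cross-population estimation with fixed-effect meta-analysis, a synthetic
    cohort generator with heritability-calibrated effect sizes, and a
    scenario-grid driver for Monte-Carlo evaluation of type-I error, bias,
    power and convergence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    data.table,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
biocViews: StatisticalMethod, GenomeWideAssociation, SNP, Regression
RoxygenNote: 7.3.3
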