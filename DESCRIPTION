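Package: twonp
Title: Additive-Dominance Marker Encodings and Hybrid Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genomic prediction for test-cross hybrids that joins classical
    mixed-model machinery with gradient-boosted trees. Builds the
    additive-centered (Z) and dominance-deviation (W) marker encodings and
    their concatenation (the 2NP feature matrix), VanRaden additive and
    Vitezica dominance genomic relationship matrices, REML variance
    components and GBLUP with one or two kernels, and a tuned leaf-wise
    gradient-boosting learner on raw dosages or the 2NP matrix. Includes
    outlier screening and two-step BLUE phenotype preparation, five
    cross-validation schemes (leave-one-year-out, rolling window, k-fold,
    and two tester-holdout designs), Pearson accuracy and chance-corrected
    selection efficiency, exact double-precision TreeSHAP attributions
    aggregated into additive versus dominance contributions, and a
    test-cross simulator with known genetic architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    xgboost,
    vcfR,
    lhs,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
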