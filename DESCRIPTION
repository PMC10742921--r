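Package: raschmf
Title: Rasch-Like Matrix Factorization for Multidimensional Measurement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration and scoring tools for multidimensional psychometric
    measurement built on alternating least squares matrix factorization with
    missing data. Provides orthonormalized person/item coordinate estimation
    with anchoring, dimensionality selection by a cross-validated
    "objectivity" statistic, a decomposition-based cell standard-error model,
    common-item equating and item banking, age-anchored calibration, linear
    0-100 construct scoring with misfit-based interpretability flags, scale
    quality statistics (reliability, separation, Shannon entropy, ROC), and a
    simulator of the assumed generative model for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    jsonlite,
    pROC,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
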