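Package: ctoutliers
Title: Robust Detection of Unwarranted CT Radiation Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated screening of computed-tomography (CT) exam metadata for
    acquisitions with unwarranted radiation exposure. Builds a predictive model
    of the volume CT dose index (CTDIvol) from patient and protocol predictors:
    LASSO variable selection by cyclic coordinate descent, an outlier-robust
    regularized regression (least-absolute-deviation loss with an l2-norm
    coefficient penalty, solved by ADMM), and flagging of exams whose actual
    dose deviates from the predicted dose by more than a multiple of the
    residual standard deviation. Includes a mean-plus-3-SD cutoff detector and
    an ordinary-least-squares residual detector for comparison, confusion-matrix
    validation metrics with confidence intervals, a synthetic-cohort generator
    for end-to-end testing, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
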