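Package: csfprofiler
Title: Data-Driven Profiling of CSF Alzheimer Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised profiling of cerebrospinal-fluid (CSF) core
    Alzheimer biomarkers (the amyloid-beta 42/40 ratio, phosphorylated tau
    and total tau). Provides inter-center concordance analysis
    (Passing-Bablok regression with bootstrap confidence intervals,
    inter-assay coefficients of variation, principal-component cohort
    overlap), full-covariance Gaussian-mixture clustering of z-scored
    biomarker profiles fitted by expectation-maximization with BIC model
    selection, prevalence-based cluster labeling with a misdiagnosis
    tolerance analysis, Youden-index diagnostic cut-offs with stratified
    bootstrap confidence intervals, and age/sex histogram matching
    validated by logistic regression. A configurable six-component
    synthetic-cohort generator emulates the joint biomarker and diagnosis
    structure of a mixed memory-clinic population for testing and
    simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
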