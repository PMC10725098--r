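Package: periomi
Title: Multiple Imputation for Partial-Mouth Periodontal Recording Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of periodontitis extent and prevalence from
    partial-mouth recording protocols by multiple imputation of nonselected
    tooth sites. Fits a joint marginal mean (logistic) and within-mouth
    pairwise correlation (linear) model to site-level binary disease
    indicators by paired generalized estimating equations with an empirical
    sandwich covariance, imputes nonselected sites by sequential sampling
    from the conditional linear family of joint binary distributions, and
    combines extent and prevalence estimates across imputation replicates by
    Rubin's rules with bootstrap within-imputation variances (MI-boot).
    Includes random-site-selection masking, full-mouth ratio estimators with
    Taylor-linearized variances, a simulation evaluation harness, and a
    synthetic full-mouth cohort generator with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
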