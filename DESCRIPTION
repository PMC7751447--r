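Package: wordlit
Title: Development and Evaluation of Word-Recognition Health Literacy Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A psychometric toolkit for building and evaluating word-recognition
    (pronunciation-based) health literacy instruments in the REALM tradition,
    with multi-language forms. Covers expert content-validity screening (Lynn's
    content validity index), administration scoring, classical test theory
    statistics (Cronbach's alpha, corrected item-total correlations, percent
    correct), a two-parameter logistic item response theory engine estimated by
    marginal maximum likelihood EM with EAP person scoring, mean/sigma linear
    equating of item parameters across language forms, likelihood-ratio tests of
    differential item functioning, smoothing-spline stratified short-form
    selection producing nested forms, convergent-validity correlations, and
    intervention-sensitivity difference-in-change analysis. A seeded synthetic
    data generator reproduces the statistical structure these analyses assume so
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
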