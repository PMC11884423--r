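Package: seamlessbin
Title: Selection-Conditional Inference for Seamless Phase II/III Trials
    with Binary Endpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and hypothesis testing for two-stage adaptive
    seamless phase II/III trials in which treatment selection at the interim
    analysis uses a short-term binary endpoint while the final comparison
    uses a long-term binary endpoint. Implements the naive maximum
    likelihood estimator, the conditional mean-adjusted estimator (CMAE)
    and the Rao-Blackwell uniformly minimum variance conditional unbiased
    estimator (UMVCUE) of the response probabilities, selection-conditional
    exact and mid-p tests for the log odds difference between the selected
    and control groups, confidence intervals obtained by test inversion,
    a bivariate binomial model for correlated binary endpoints, and a
    simulation engine for operating characteristics (bias, RMSE, type-I
    error, power, coverage).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
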