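Package: circout
Title: Outlier Detection for Linear-Circular Nonparametric Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Robust detection of response-variable outliers in nonparametric
    regression of an angular response on a linear predictor. Provides
    circular-statistics primitives (circular distance, mean direction,
    circular median), the wrapped Cauchy distribution (density, distribution
    function, sampling, moment and maximum-likelihood estimation),
    Nadaraya-Watson and local-linear circular-response kernel estimators with
    leave-one-out cross-validated bandwidths, Monte-Carlo calibration of
    detection cut-off points based on distances of absolute circular
    residuals from their circular median, a parametric-bootstrap cut-off for
    applied data, a Watson U-squared goodness-of-fit test for the wrapped
    Cauchy assumption with bootstrap critical values, and a simulation-study
    runner reporting true detection, masking and swamping rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
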