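Package: gmoee
Title: Generalized Marshall-Olkin Exponentiated Exponential Distribution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Density, distribution, survival, hazard, quantile and random
    generation for the four-parameter generalized Marshall-Olkin
    exponentiated exponential (GMO-EE) lifetime distribution, together with
    its moment machinery (moment-generating function, raw and incomplete
    moments, Lorenz and Bonferroni curves), five frequentist estimators
    (maximum likelihood, least squares, weighted least squares,
    Anderson-Darling and Cramer-von Mises minimum distance), goodness-of-fit
    reporting against exponentiated-exponential, Weibull and exponential
    baselines, and a Monte Carlo harness for estimator bias/MSE comparison.
    Ships four classical positive lifetime datasets (air-conditioning
    failures, New York ozone levels, Wheaton River flood exceedances,
    COVID-19 recovery times) as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    lhs,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
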