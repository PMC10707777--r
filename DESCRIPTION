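Package: chronoprof
Title: Chrono-Nutritional Profiling of 24-Hour Eating Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive chrono-nutritional profiles from binary
    meal-contact diaries recorded over the 24-hour day. Eleven predefined
    eating occasions (main meals, snacks, nibbling slots) are expanded into
    hourly step functions, smoothed with a roughness-penalized Fourier basis
    (order 2, smoothing parameter chosen by pooled generalized
    cross-validation), and clustered with a parsimonious Gaussian
    subspace-mixture model for functional data fitted by EM, with the number
    of profiles selected by BIC. The package also provides chained-equation
    imputation with predictive mean matching, median (quantile 0.5)
    regression and logistic regression with backward AIC selection,
    descriptive test batteries, and a calibrated synthetic-cohort generator
    so the full pipeline can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    withr,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
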