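Package: reci
Title: Cause-Effect Inference by Comparing Regression Errors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Infers the causal direction between two observed variables by
    fitting least-squares regressions in both directions and comparing the
    run-averaged test mean squared errors (the RECI procedure). Includes the
    regression family zoo (logistic, shifted monomial, polynomial, linear
    support-vector, small neural nets), min-max and z-score scaling with
    kernel-density-based removal of low-density points, synthetic
    cause-effect-pair generators with dependent noise and a small-noise
    theorem-regime generator, numerical verification of the error-asymmetry
    theorem (quadrature of the limiting variance ratio, independence-postulate
    checks, binned conditional-variance estimation), and an evaluation harness
    with weighted accuracy and decision-rate curves for Tuebingen-style
    cause-effect pair files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    ggplot2,
    generics,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
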