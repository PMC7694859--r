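Package: echoref
Title: Body-Weight-Dependent Reference Intervals for Canine
    Echocardiographic Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Allometric-scaling reference intervals for left-ventricular
    M-mode measurements in dogs. Fits power-law models Y = a * BW^b on the
    log scale, constructs exact and approximate 95% prediction intervals,
    derives percentile indexing constants, screens outliers with Tukey-type
    quartile fences, validates model linearity with penalized-spline
    smoothers, classifies breeds as deviant by the fraction of measurements
    outside the population prediction intervals, and decomposes
    interobserver variance with a random-examiner-intercept model. Includes
    a synthetic-cohort generator that emulates the structure of a large
    multicenter breeding-screen database so the whole pipeline is testable
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    splines,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
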