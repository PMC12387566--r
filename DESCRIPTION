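Package: growthlms
Title: Growth Reference Construction with the LMS (Box-Cox Cole-Green) Method
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing and using pediatric growth references by
    the LMS method (the Box-Cox Cole-Green distribution): z-scores, centiles
    and quantile inversion; penalized-likelihood estimation of age-varying
    (mu, sigma, nu) curves with two-part stitched age models, monotone-median
    enforcement and worm-plot diagnostics; anthropometric data cleaning with
    robust percentile-based outlier filters; derivation of overweight and
    obesity cut-offs anchored at BMI 25 and 30 kg/m2 at age 18; prevalence
    and burden-share tables stratified by parental origin; contingency-table
    tests of regional representation in extreme centile bands; and a
    calibrated synthetic cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
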