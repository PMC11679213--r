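Package: renalbmd
Title: Benchmark Dose Analysis of Urinary Cadmium for Renal Effect Markers
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for benchmark-dose (BMD) analysis of urinary cadmium
    against renal tubular and glomerular effect markers. Derives renal
    endpoints (2-h creatinine clearance, the Japanese Society of Nephrology
    eGFR equation, creatinine-corrected urinary analytes, percent tubular
    reabsorption of beta2-microglobulin) from raw analytes, fits
    age-adjusted linear and logistic dose-response models stratified by
    sex, and computes BMDs and one-sided lower confidence limits (BMDLs)
    by the hybrid approach for continuous endpoints and by additional or
    extra risk for dichotomous endpoints, with profile-likelihood, delta
    and slope-bound BMDL methods. Includes a calibrated synthetic-cohort
    generator for validation by parameter recovery, plus a command-line
    pipeline emitting report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
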