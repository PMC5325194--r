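Package: oxytitrate
Title: Oxygen Conservation from Routine Titration in Pediatric Oxygen Therapy
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte Carlo model of medical-oxygen consumption by pediatric
    hypoxemic-pneumonia patients under routine flow titration. Samples
    synthetic cohorts from discrete distributions of starting flow rate,
    treatment duration and piecewise-linear weaning profile, computes the
    oxygen volume used under zero-order-hold titration policies (no routine
    titration, every 24 hours, every 3 minutes, or any interval), and
    summarises paired-scenario cohort totals and savings fractions across
    replicates. An exact enumeration oracle over the finite parameter
    support provides closed-form expectations, variances and predicted
    replicate standard errors for validating every simulated quantity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
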