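Package: dihia
Title: Diisocyanate Exposure Reconstruction and Health Impact Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for occupational diisocyanate (MDI, TDI, HDI, IPDI)
    exposure assessment from left-censored air and urinary biomonitoring
    data. Implements LOQ/2 substitution for censored records, conversion of
    diisocyanate air levels to reactive NCO mass, creatinine unit
    conversion, empirical-quantile (piecewise-linear inverse CDF) exposure
    distributions, reverse dosimetry by Bayesian Metropolis-Hastings
    inversion of a one-compartment linear kinetic model (MDI/TDI) and by
    log-log regression calibration (HDI), Monte Carlo integration of
    reconstructed air exposure, a capped monotone-spline excess-risk
    dose-response for bronchial hyperresponsiveness, and sector-level
    excess-case estimation. A seeded synthetic-data generator emulates the
    skewed, heavily censored structure of occupational biomonitoring
    registries so the full chain is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
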