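Package: popadjust
Title: Population-Adjusted Indirect Treatment Comparisons with Limited
    Individual Patient Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for anchored and unanchored population-adjusted indirect
    comparisons when individual patient data (IPD) are available for one
    trial (AB) and only published aggregate data for another (AC).
    Implements matching-adjusted indirect comparison (MAIC) with
    method-of-moments weight estimation and an entropy-balancing variant,
    simulated treatment comparison (STC) outcome regression with
    effect-modifier interactions and covariate-distribution averaging,
    Bucher-style standard indirect comparisons, robust sandwich and
    bootstrap variance estimation, effective-sample-size and weight
    diagnostics, transport of contrasts to a stated target population under
    a shared effect modifier assumption, and a simulation engine for
    assessing bias and coverage of the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
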