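Package: ezcua
Title: Markov Cohort Cost-Utility Model of Ezetimibe Add-On Therapy After
    Acute Coronary Syndrome
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-analytic cost-utility modelling of ezetimibe added to
    moderate-intensity statin therapy versus moderate-intensity statin
    therapy alone for secondary prevention after acute coronary syndrome,
    from societal and healthcare-provider perspectives. Implements a
    four-state annual-cycle Markov cohort model (no further event,
    non-fatal myocardial infarction, non-fatal stroke, death) with
    life-table background mortality, hazard-ratio and relative-risk
    adjustment, half-cycle correction and discounting; method-of-moments
    fitting of beta, gamma and log-normal parameter distributions from
    point estimates and interval bounds; one-way (tornado) sensitivity
    analysis; and seeded Monte-Carlo probabilistic sensitivity analysis
    with cost-effectiveness plane quadrant shares and acceptability
    curves. Includes a deterministic Gompertz-Makeham synthetic
    life-table generator for use when a national life table is not
    available.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
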