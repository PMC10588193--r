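Package: rxscreen
Title: Prescription Risk Screening, Alerting and Response Analytics for
    Controlled Substances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens opioid and benzodiazepine prescription orders against
    patient-history risk triggers (early refill, repeated on-site
    administration, prescription frequency, prior overdose, positive
    toxicology, co-prescribing, extended-release orders to opioid-naive
    patients) the way an EHR-embedded clinical decision support rule does,
    computes morphine milligram equivalent doses, classifies prescriber
    responses to the resulting alerts into a continued / cancelled /
    none-ordered taxonomy, generates synthetic longitudinal EHR event
    streams with configurable risk-factor prevalences, and analyses
    decision-influenced rates with stratified tables, chi-square and
    Cochran-Armitage trend tests, and Shewhart p-charts with special-cause
    detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
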