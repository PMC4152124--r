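Package: offlabelr
Title: Drug Utilisation and Off-Label Prescribing Analysis for Paediatric
    Respiratory Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for analysing drug utilisation and off-label
    prescribing of respiratory drugs in children from claims-style data: a
    drug-label knowledge base (approved minimum age and ICD-10 indication
    prefixes per ATC code), a three-way off-label classifier (age, indication,
    age and indication), annual period prevalence rates with insurance-coverage
    correction and age/gender stratification, trend measures, and a synthetic
    claims-data generator with ground truth so every stage is testable without
    access to a real claims database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
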