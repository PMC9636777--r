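Package: uticost
Title: Appropriateness of Antibiotic Prescribing and Healthcare Costs in
    Uncomplicated Urinary Tract Infection
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for studying suboptimal and inappropriate
    antibiotic prescribing in uncomplicated urinary tract infection (uUTI)
    from EHR-style tables: index-event identification and an auditable
    inclusion/exclusion waterfall, a guideline-based rule engine that
    adjudicates treatments as appropriate, inappropriate or suboptimal,
    person-level antimicrobial susceptibility aggregation, healthcare
    resource use and cost construction from a configurable fee schedule,
    1:1 propensity-score-matched gamma log-link cost regression with
    covariate balance diagnostics, and a sensitivity-analysis battery.
    Includes a seeded synthetic EHR generator with planted ground truth so
    every stage can be tested against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
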