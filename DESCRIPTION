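Package: respaudit
Title: Respiratory Care Resource Audits and Pediatric Hypoxemia Cohort Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing tiered respiratory care resource availability
    at resource-constrained hospital sites and for analysing cohorts of
    hypoxemic children. Scores 5-point Likert facility surveys into tiered
    resource bundles (none through expert), constructs hypoxemia cohorts from
    daily case-report records, computes bedside severity scores (Lambarene
    Organ Dysfunction Score, malnutrition), operationalizes the PALICC-2
    classification of pediatric acute respiratory distress syndrome (PARDS,
    Possible PARDS, At-risk) including its data-sufficiency screen, and links
    resource availability and PARDS triggers to in-hospital mortality through
    contingency tables, rank tests, and logistic regression fitted by
    iteratively reweighted least squares. A synthetic-cohort generator and a
    deterministic reference fixture support validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
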