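Package: phenocad
Title: Rules-Based Phenotyping of Coronary Artery Disease from Linked
    Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable engine for rules-based, multi-source electronic
    health record (EHR) phenotyping of coronary artery disease (CAD) in
    biobank-style cohorts. Classifies every participant into one of six
    mutually exclusive CAD sub-phenotypes (prevalent/incident myocardial
    infarction, prevalent/incident CAD without MI, and their self-reported
    counterparts) or one of two control labels, from linked hospital
    diagnosis (ICD-10/ICD-9), procedure (OPCS-4), death-registry and
    baseline questionnaire tables, driven by replaceable code lists.
    Includes the two fidelity-evaluation procedures used to validate such
    phenotypes - age/sex-adjusted Cox mortality gradients and per-standard-
    deviation polygenic risk score association gradients with greedy LD
    clumping - plus a fully linked synthetic biobank generator with planted
    ground truth so every stage is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
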