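Package: ldxdur
Title: Drug Utilization Analysis of Lisdexamfetamine Prescription Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds treatment episodes from longitudinal prescription event
    tables, computes exposure duration and average daily dose, classifies
    medication discontinuation and switching using 30-day grace-period
    definitions, and audits lisdexamfetamine (LDX) prescriptions against
    country- and date-specific label rules (recorded ADHD diagnosis, prior
    methylphenidate use, minimum age, maximum daily dose, adult approval
    status). Includes a synthetic multi-country cohort generator emulating
    European registry and prescription-database structure, so the complete
    pipeline is testable without access to real registry data, and reporting
    helpers producing cohort summaries of demographics and treatment patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
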