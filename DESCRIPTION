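Package: pvsignal
Title: Pharmacovigilance Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for disproportionality-based signal
    detection in spontaneous-reporting pharmacovigilance data distributed as
    FAERS-style quarterly delimited-text bundles. Reads DEMO/DRUG/REAC/OUTC/
    THER/INDI tables, applies case-version deduplication and deleted-report
    removal, selects a pediatric cohort of psychiatric adverse events
    attributed to respiratory drugs (WHO ATC "R" category, primary-suspect
    role, MedDRA psychiatric-disorders System Organ Class), and computes four
    disproportionality statistics (reporting odds ratio, proportional
    reporting ratio, the MHRA chi-squared criterion, and the BCPNN
    information component) with a conservative all-four composite signal
    rule, descriptive frequency tables, MedDRA high-level-group-term rollups,
    and age/sex-stratified analyses. A synthetic report generator with
    injected signals of known strength makes every stage testable without
    access to the source database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
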