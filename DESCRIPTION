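Package: pvsignal
Type: Package
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance pipeline for spontaneous
    adverse-event reporting data in the FAERS quarterly ASCII dialect:
    ingestion and case-level deduplication, primary-suspect filtering,
    MedDRA PT-to-SOC mapping, drug-event 2x2 contingency construction,
    and four disproportionality statistics (reporting odds ratio,
    proportional reporting ratio with Pearson chi-square, BCPNN
    information component, and the multi-item gamma-Poisson shrinker
    EBGM) with joint signal thresholds. Includes stratified,
    concomitant-exclusion, comparator, demographic and time-to-onset
    analyses, and a synthetic report generator with analytically known
    ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
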