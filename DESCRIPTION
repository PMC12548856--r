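Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance signal detection on
    FDA Adverse Event Reporting System (FAERS) style quarterly ASCII data:
    ingestion and validation of the six '$'-delimited tables, case-level
    deduplication (latest FDA_DT, ties broken by PRIMARYID), drug-name
    standardization via synonym dictionaries, MedDRA-style PT to SOC
    mapping, construction of drug-event 2x2 contingency tables, and
    disproportionality statistics (reporting odds ratio, proportional
    reporting ratio, Pearson/Yates chi-square, and the BCPNN information
    component) with threshold screening, ranking, sex stratification,
    descriptive summaries, and a synthetic report generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
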