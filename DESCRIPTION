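Package: cdmprivacy
Title: Privacy Risk Quantification for OMOP Common Data Model Research Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Quantifies re-identification risk of personal health identifiers
    (PHIs) and quasi-identifiers (QIs) in OMOP Common Data Model (CDM) tables,
    as used in distributed research networks. Builds per-identifier limited
    data sets and clinical-scenario data sets, applies HIPAA safe-harbor
    masking (date generalisation and suppression), profiles k-anonymity
    equivalence classes, computes minimum-cell-size percentages, maximum
    equivalence-class sizes and trust-differential gaps between
    deidentification levels, and runs paired random-sampling experiments to
    compare risk at equal record counts. Includes a configurable synthetic
    CDM generator emulating the structure of the SynPUF 5% public release so
    the full pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    data.table (>= 1.14.0),
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
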