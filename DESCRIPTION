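Package: pumpconcord
Title: Reconciling Smart Infusion Pump Records with EHR Medication Orders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating smart infusion pump event logs with
    electronic health record (EHR) ordering and administration data to
    detect medication administration discrepancies in continuous
    infusions. Provides validity screening of pump records (patient-ID
    and drug-library checks with a nine-way taxonomy of invalid IDs),
    timestamp-based linkage of pump records to medication orders,
    rule-based dose/rate discrepancy detection with a 30-minute verbal
    order grace window, magnitude-of-discrepancy quantification and
    binning, event-block segmentation of order timelines, and a
    block-level concordance assessment (Cohen's kappa) between
    EHR-documented and pump-logged discrepancies. Includes a synthetic
    paired EHR/pump event-stream generator with a ground-truth error
    ledger so the full pipeline is testable without protected health
    information.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
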