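Package: sedetl
Title: Pharmacy Packing-System ETL and Sedative Medication Auditing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An extract-transform-load and audit pipeline for sedative
    (antipsychotic and benzodiazepine) medication use in nursing homes.
    Reads resident and medication exports from pharmacy packing systems in
    two delimited dialects, maps vendor medication codes through an
    AMT-style medicines terminology (TPUU/CTPP to MPUU) onto WHO ATC codes,
    classifies antipsychotics and benzodiazepines, parses dosing
    instructions into daily doses and WHO Defined Daily Dose (DDD) ratios,
    and aggregates per-resident sedative load in diazepam and
    chlorpromazine milligram equivalents. A four-phase validation and
    verification workflow (unmapped-medication resolution, off-site
    validation, in-home verification, retrospective cleaning) runs over an
    append-only transaction log with deterministic replay, duplicate
    resident merging, and per-phase correction accounting. Includes a
    synthetic data generator with configurable injected error modes and a
    ground-truth ledger, per-home prevalence and sedative-load reports,
    coverage statistics, a pooled two-proportion z-test, and interaction
    session-time estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
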