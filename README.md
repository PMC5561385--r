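# sedetl

An event-sourced ETL and validation pipeline for auditing sedative
(antipsychotic and benzodiazepine) medication use in nursing homes from
pharmacy packing-system exports.

Community pharmacies that pack medications for nursing homes hold, as a
by-product of packing, a near-complete record of what every resident is
taking. `sedetl` turns those packing exports into auditable prevalence
statistics through five stages:

1. **Ingest** — parse plain-text packing exports (two dialects: a sectioned
   `table_export` and a flat `report` format), pseudonymize residents with a
   keyed SHA-256 digest of the normalized name and birth date, link pharmacy
   wing names to participating homes, and assemble point-in-time snapshots.
2. **Enrich** — resolve each vendor medication code through an AMT-style
   concept hierarchy (CTPP → TPP → TPUU → MPUU) to a generic
   unit-of-use concept, attach ATC codes, classify sedatives by ATC prefix
   rules (N05A antipsychotics excluding lithium and prochlorperazine; N05BA /
   N05CD / N05CF / N03AE01 benzodiazepines and related drugs), detect PRN
   ("as required") dosing, parse dosing instructions with a small additive
   grammar, and compute daily doses.
3. **Validate** — a four-phase human workflow over an append-only
   transaction log: unmapped-code resolution by a research pharmacist (P1),
   off-site correction of obvious errors (P2), in-home verification by a
   champion nurse who also enters omitted medications (P3), and
   retrospective cleaning, chiefly duplicate-profile merges (P4). State is a
   pure function of the initial snapshot and the log; replaying the log
   reproduces the live state exactly.
4. **Verify** — a home unlocks reporting only when every resident has been
   checked and no blocking flags (missing packed quantity, unresolved
   mapping) remain on its sedative records.
5. **Report** — per-home prevalence of regular and PRN sedative use,
   sedative load in diazepam / chlorpromazine milligram equivalents scaled
   by WHO Defined Daily Dose (DDD) ratios, coverage and correction-share
   statistics, a pooled two-proportion z-test, and session-time estimates.

A full synthetic-data generator (`generate_pharmacy_data`) produces
realistic exports with injected error modes — omitted records, missing
quantities, transposed fields, unmapped codes, duplicate split-pack
profiles — together with a ground-truth ledger, so the entire pipeline is
testable offline: after applying the generated correction session, the final
state must recover the ledger exactly.

## Worked example

```r
library(sedetl)

dir <- file.path(tempdir(), "demo")
cfg <- generator_config(seed = 42, n_homes = 2)
bundle <- generate_terminology(cfg)
truth <- generate_pharmacy_data(cfg, bundle, dir)
basename(truth$files)
#> [1] "P01.table_export.txt" "P02.report.txt"

pre <- run_pipeline(truth$files, bundle, truth$registry,
                    key = "demo-key", timestamp = "2015-07-01")
unlist(pre$summary[c("medications_extracted", "sedative_records",
                     "unmapped_remaining")])
#> medications_extracted      sedative_records     unmapped_remaining
#>                  2606                   115                      1

list_unmapped(pre$state)
#>       vendor vendor_code              med_name n
#> 1 alpha_pack    Xg000260 oxazepam 15 mg tablet 1

# apply the four-phase correction session, then report
session <- generate_session_log(truth, pre$state)
post <- run_pipeline(truth$files, bundle, truth$registry,
                     key = "demo-key", timestamp = "2015-07-01",
                     corrections = session$corrections)
unlist(post$summary$homes)
#>        H01        H02
#> "VERIFIED" "VERIFIED"

post$reports[["H01"]]
#>   home_id snapshot_label n_residents pct_on_antipsychotic_regular
#> 1     H01       baseline         126                        15.87
#>   pct_on_benzodiazepine_regular pct_on_antipsychotic_prn
#> 1                         21.43                     8.73
#>   pct_on_benzodiazepine_prn mean_diazepam_equiv_mg mean_chlorpromazine_equiv_mg
#> 1                      12.7               2.395503                     13.09028

recovery_rate(truth, post$state)$rate
#> [1] 1

print(two_proportion_ztest(586, 16179, 812, 13272))
#> Two-proportion z-test: z = -10.02, two-tailed p < .001
#>   p1 = 0.0362, p2 = 0.0612, pooled = 0.0475
```

`run_synthetic_study()` wraps the generate → ingest → correct → verify loop
in one call. A thin command-line wrapper is installed at
`system.file("cli", "sedetl.R", package = "sedetl")` with `synth`, `run` and
`ztest` subcommands (exit codes: 0 success, 2 gating, 3 integrity,
4 format).

## Reproduction

`scripts/acceptance.R` computes every headline quantity at runtime — the
pooled z statistic on the published omission counts, the coverage and
per-phase correction shares, and the end-to-end synthetic recovery under the
default (study-condition) generator configuration — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

Each entry has the form `{"<id>": {"value": <number>, "n": <size>}}`, with
values on the scale at which they are conventionally printed (percentages at
two decimal places, rounded half away from zero).

## Package layout

| File | Contents |
| --- | --- |
| `R/terminology.R` | concept hierarchy, vendor-code resolution, ATC/DDD tables, manual mappings |
| `R/ingest.R` | export dialects, pseudonymization, wing linking, snapshots |
| `R/classify.R` | ATC prefix rules, PRN detection, snapshot enrichment |
| `R/doseload.R` | sig grammar, daily doses, DDD ratios, equivalent loads |
| `R/validation.R` | transaction log, four-phase corrections, merges, flags, replay |
| `R/reporting.R` | prevalence, coverage, z-test, session-time estimates |
| `R/synthdata.R` | synthetic generator and ground-truth ledger |
| `R/pipeline.R` | end-to-end wrapper and recovery measurement |

See `vignettes/sedative-audit-pipeline.Rmd` for the methods behind each
stage and the numerical conventions.
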