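---
title: "Methods: auditing sedative use from pharmacy packing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditing sedative use from pharmacy packing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedetl)
```

## The problem and the data model

Nursing-home medication audits traditionally require manual chart review.
Community pharmacies that pack medications into dose-administration aids
already hold, in their packing software, a structured record of every
resident's current medications. `sedetl` models the pathway from those
packing exports to verified, per-home sedative prevalence statistics.

The data model has four layers:

* **Exports.** Plain-text files in one of two dialects standing in for the
  heterogeneous proprietary formats of packing systems: `table_export`
  (sectioned `[residents]` / `[medications]` / `[wings]` tables) and
  `report` (repeated `RES` line + `MED` lines blocks). Every file opens
  with a header declaring its dialect and vendor. Malformed rows are never
  dropped silently; they land in a reject table with line numbers.
* **Terminology.** An AMT-style concept hierarchy. Packing systems identify
  products at either trade-product unit-of-use (TPUU) or
  containered-trade-product pack (CTPP) level; both resolve along
  `CTPP -contains-> TPP -contains-> TPUU -is_generic_of-> MPUU` to a unique
  medicinal-product unit-of-use (MPUU), which carries the ATC
  assignment(s) and strength. Validation enforces the single-parent
  invariants that make the walk deterministic, and resolution is verified
  against brute-force path enumeration in the test suite.
* **Snapshots.** A point-in-time upload: pseudonymized residents, their
  active medication rows (records ceased before the snapshot timestamp are
  excluded and counted), and the wing-to-home assignment. Pseudonyms are
  keyed SHA-256 digests of the normalized name (case-folded, punctuation
  stripped, tokens sorted, so `"SMITH, John"` equals `"john smith"`) plus
  birth date; the same person reappearing under a name variant therefore
  collides on the identity key, which is how duplicate split-pack profiles
  are proposed for merging.
* **Event-sourced state.** All human corrections are entries in an
  append-only transaction log; live state is a pure function of the initial
  snapshot and the log. Cascades (deleting a resident soft-deletes their
  medications) are recorded as system-authored entries, so `replay()` over
  the initial state reproduces the live state exactly. This is the
  correctness backbone: the test suite replays hundreds of randomized
  correction sessions and requires bit-for-bit state equality.

## Classification and dose model

A medication is a **sedative** when any of its MPUU's ATC assignments
matches the rule set: prefix `N05A` (antipsychotics) excluding `N05AN`
(lithium) and `N05AB04` (prochlorperazine), or prefixes `N05BA`, `N05CD`,
`N05CF`, `N03AE01` (benzodiazepines and related drugs). ATC membership is
string-prefix membership and the longest matching prefix wins, so an
exclusion always beats the inclusion it refines while siblings of an
excluded code (`N05AB03`) stay included. Checking *all* assignments matters
for combination products whose sedative component is a secondary
assignment; when a secondary sedative code wins, it also becomes the
record's working ATC code so DDD lookups stay within the sedative class.
The rule set is configuration (`inst/extdata/rules.yaml`), not code.

**PRN** ("pro re nata") status comes from the vendor's own flag when
present; otherwise from case-insensitive whole-token matches of `prn`,
`as required`, `when required`, `as needed` in the instruction text.

**Daily dose** uses a deliberately small additive grammar over pharmacy sig
shorthand: each part is a count (integer, decimal, or word; `half` = 0.5)
times a frequency token (`mane`/`nocte`/`midday`/`daily`/`od` = 1, `bd` =
2, `tds` = 3, `qid` = 4), summed over `and`-separated parts. Anything
outside the grammar is returned as `unparseable` and flagged for human
review rather than guessed — in this design, refusing to parse is a
feature, since unparseable instructions are exactly what phase-2 validation
exists to fix.

**Sedative load** is expressed in reference-drug milligram equivalents:
diazepam (`N05BA01`) for benzodiazepines, chlorpromazine (`N05AA01`) for
antipsychotics. The default conversion scales by Defined Daily Dose ratio,
`dose / DDD(drug) × DDD(reference)`, which is exact for the reference drug
and linear in dose; a per-drug clinical equivalence table, when supplied,
overrides the default. PRN sedatives are excluded from load sums (packing
data cannot tell how much of a PRN supply is actually taken) and counted
separately.

## The validation workflow

Corrections happen in four phases, each logged with its actor role:

1. **P1 mapping** — a research pharmacist maps vendor codes the automatic
   linkage missed, either directly or as a *chemically equivalent*
   fallback; fallback-mapped records keep displaying the vendor's
   medication name so nursing staff always see what the prescription said.
2. **P2 off-site** — project staff fix obvious extraction errors
   (e.g. transposed fields) before anyone visits the home.
3. **P3 in-home** — the champion nurse checks every resident, enters
   missing quantities and medications the packing export omitted (PRN items
   are omitted more often than regular ones, since un-packed medications
   may never reach the pharmacy's packing module).
4. **P4 retrospective** — duplicate split-pack profiles are merged; exact
   duplicate rows (same drug, schedule and dates) collapse to the earliest
   record.

Reports are gated: a home is `VERIFIED` only when every active resident is
checked and no blocking flags (missing packed quantity, unresolved mapping)
remain on its sedative records. Dose-range flags (daily dose strictly above
4 × DDD, or exactly zero) are advisory. Flags are always recomputed from
current state, never stored, so they cannot go stale.

## The synthetic generator

Real packing exports cannot be shipped, so the package carries a generator
whose defaults mirror the audited setting's magnitudes: ~90 residents per
home (SD 37.5), ~11.84 medication records per resident, 5.13% of records
sedative, 45.06% of sedatives PRN, 11.07% duplicate resident profiles, PRN
and regular omission rates of 6.12% and 3.62%, plus configurable rates for
missing quantities (8%), transposed fields (2%) and unmapped codes (1%).
Every generated record and every injected fault is written to a
ground-truth ledger, and `generate_session_log()` derives the four-phase
correction session that exactly repairs the injections. The central
end-to-end property — enforced in the acceptance tests at error rates 0,
0.05, 0.25 and 1 — is that after applying the session, `recovery_rate()`
is exactly 1: every ledger record is present once, with the true class, PRN
status, daily dose and quantity, under the merged primary profile.

Scope limits worth knowing: the generator draws drugs independently per
record, so resident-level sedative prevalence runs higher than a setting
where sedative use concentrates in fewer residents; names come from a fixed
32×32 pool with uniqueness enforced on (name, birth date); and the drug
catalogue's DDD values are synthetic-but-plausible placeholders with the
same schema as the WHO reference values, which drop in unchanged. Synthetic
runs therefore exercise every code path and invariant but make no claim to
reproduce any real study's exact counts.

## Numerical conventions and resolved ambiguities

* **Rounding.** All printed percentages round half away from zero at two
  decimal places (`round_half_away`), not banker's rounding. Where source
  material prints the same ratio inconsistently at the last digit, this
  package computes the half-away-from-zero value and documents the choice
  rather than emulating the inconsistency.
* **z-test.** The two-proportion test is the pooled normal approximation
  without continuity correction; on omission counts 586/16,179 versus
  812/13,272 it gives z = −10.02 (two-tailed p < .001), which the
  acceptance suite pins at two decimals. A degenerate pooled proportion
  (0 or 1) yields `z = NA`, p = 1.
* **Timestamps** are always explicit inputs; nothing reads the wall clock,
  so every pipeline run is reproducible byte for byte.
* **Session time** aggregates interaction events into blocks separated by
  gaps above 10 minutes (configurable); a block's duration is last minus
  first event, and lone events contribute zero.
* **Problem sizes** (homes, residents per home, records per resident) are
  package configuration with study-scale defaults; tests that need larger
  sedative denominators change only the record-mix composition, never the
  error rates under test.

## A minimal run

```{r example, eval = FALSE}
study <- run_synthetic_study(generator_config(seed = 1))
recovery_rate(study$truth, study$result$state)$rate  # 1
study$result$reports[["H01"]]
correction_stats(study$result$state$log)
```
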