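# Event-sourced validation workflow: log entries, corrections, cascades,
# merges, flags, verification gating, replay and persistence.

test_that("log entries enforce their vocabulary and modify contract", {
  expect_error(log_entry("P9", "system", "add", "resident", "x"),
               "phase")
  expect_error(log_entry("P1_mapping", "intern", "add", "resident", "x"),
               "actor_role")
  expect_error(log_entry("P2_offsite", "project_staff", "modify",
                         "medication", "m000001"),
               class = "sedetl_contract_error")
  e <- log_entry("P2_offsite", "project_staff", "modify", "medication",
                 "m000001", sedetl:::fc("quantity_supplied", NA, 28))
  expect_s3_class(e, "sedetl_log_entry")
})

test_that("corrections modify, add and delete with full logging", {
  st <- mini_state()
  mid <- st$medications$med_id[1]
  st2 <- apply_correction(st, log_entry(
    "P3_inhome", "champion_nurse", "modify", "medication", mid,
    sedetl:::fc("quantity_supplied", 28, 56)))
  expect_equal(active_medications(st2)$quantity_supplied[1], 56L)
  expect_equal(nrow(st2$log), 1L)
  expect_equal(st2$log$action, "modify")
  # the input state is untouched (value semantics)
  expect_equal(active_medications(st)$quantity_supplied[1], 28L)

  rid <- active_residents(st2)$resident_id[1]
  add <- log_entry("P3_inhome", "champion_nurse", "add", "medication",
                   "a000001",
                   sedetl:::fc(c("resident_id", "home_id", "vendor",
                                 "vendor_med_id", "med_name", "class", "prn",
                                 "daily_dose_mg", "source"),
                               NA,
                               c(rid, "H01", "alpha_pack",
                                 code_of("oxazepam"), "oxazepam 15 mg tablet",
                                 "BENZODIAZEPINE", FALSE, 15, "manual")))
  st3 <- apply_correction(st2, add)
  added <- active_medications(st3)
  added <- added[added$med_id == "a000001", ]
  expect_equal(added$class, "BENZODIAZEPINE")
  expect_equal(added$daily_dose_mg, 15)
  expect_false(added$prn)
  expect_false(added$deleted)
  # adding the same id twice, or for an unknown resident, is an error
  expect_error(apply_correction(st3, add), class = "sedetl_integrity_error")
  bad <- log_entry("P3_inhome", "champion_nurse", "add", "medication",
                   "a000002", sedetl:::fc("resident_id", NA, "ghost"))
  expect_error(apply_correction(st3, bad), class = "sedetl_integrity_error")
  expect_error(apply_correction(st3, log_entry(
    "P2_offsite", "project_staff", "modify", "medication", "nope",
    sedetl:::fc("prn", NA, TRUE))), class = "sedetl_integrity_error")
  expect_error(apply_correction(st3, log_entry(
    "P2_offsite", "project_staff", "modify", "medication", mid,
    sedetl:::fc("no_such_field", NA, "x"))),
    class = "sedetl_integrity_error")

  st4 <- apply_correction(st3, log_entry(
    "P2_offsite", "project_staff", "delete", "medication", "a000001"))
  expect_false("a000001" %in% active_medications(st4)$med_id)
  # soft delete: the row survives in the underlying table
  expect_true("a000001" %in% st4$medications$med_id)
})

test_that("deleting a resident cascades to their medications as system entries", {
  st <- mini_state()
  res <- active_residents(st)
  rid <- res$resident_id[res$source_key == "R001"]
  n_meds <- sum(active_medications(st)$resident_id == rid)
  expect_gt(n_meds, 0)
  st2 <- apply_correction(st, log_entry(
    "P2_offsite", "project_staff", "delete", "resident", rid))
  expect_false(rid %in% active_residents(st2)$resident_id)
  expect_equal(sum(active_medications(st2)$resident_id == rid), 0L)
  expect_equal(nrow(st2$log), 1L + n_meds)
  expect_equal(sum(st2$log$actor_role == "system"), n_meds)
  expect_true(all(st2$log$action == "delete"))
})

test_that("mapping corrections re-enrich the affected records", {
  st <- mini_state()
  zz <- st$medications[st$medications$vendor_med_id == "ZZ9999", ]
  expect_equal(zz$class, "PENDING")
  cat <- fixture_catalogue()
  target <- cat$tpuu1_id[cat$drug == "nitrazepam"]
  st2 <- apply_correction(st, log_entry(
    "P1_mapping", "research_pharmacist", "add", "mapping",
    "alpha_pack:ZZ9999",
    sedetl:::fc(c("target_concept_id", "origin", "equivalent_of_name"),
                NA, c(as.character(target), "equivalent_fallback",
                      "mystery elixir"))))
  zz2 <- st2$medications[st2$medications$vendor_med_id == "ZZ9999", ]
  expect_equal(zz2$class, "BENZODIAZEPINE")
  expect_equal(zz2$mpuu_id, cat$mpuu_id[cat$drug == "nitrazepam"])
  expect_equal(zz2$atc_code, "N05CD02")
  expect_equal(zz2$daily_dose_mg, 5)   # One tablet mane x 5 mg
  # display name still shows what the prescription said
  expect_equal(zz2$display_name, "mystery elixir")
  expect_equal(nrow(list_unmapped(st2)), 0L)
  # a second mapping for the same code conflicts
  expect_error(apply_correction(st2, log_entry(
    "P1_mapping", "research_pharmacist", "add", "mapping",
    "alpha_pack:ZZ9999",
    sedetl:::fc(c("target_concept_id", "origin"), NA,
                c(as.character(target), "manual")))),
    class = "sedetl_conflict_error")
})

test_that("duplicate proposal and merge collapse split-pack profiles", {
  st <- mini_state()
  prop <- propose_duplicates(st)
  expect_equal(nrow(prop), 1L)
  expect_equal(prop$score, 1)
  src <- prop$source; tgt <- prop$target
  src_meds <- sum(active_medications(st)$resident_id == src)
  tgt_meds <- sum(active_medications(st)$resident_id == tgt)
  st2 <- merge_residents(st, src, tgt)
  expect_false(src %in% active_residents(st2)$resident_id)
  expect_equal(st2$residents$merged_into[st2$residents$resident_id == src],
               tgt)
  # no shared drugs between the two profiles here, so counts just add
  expect_equal(sum(active_medications(st2)$resident_id == tgt),
               src_meds + tgt_meds)
  expect_error(merge_residents(st, src, src),
               class = "sedetl_contract_error")
  expect_error(merge_residents(st, "ghost", tgt),
               class = "sedetl_integrity_error")
  expect_error(merge_residents(st2, tgt, src),
               class = "sedetl_contract_error")  # target already merged away
})

test_that("merging collapses exact duplicate rows but keeps distinct drugs", {
  st <- mini_state()
  prop <- propose_duplicates(st)
  src <- prop$source; tgt <- prop$target
  # copy one of the target's rows onto the source profile (exact split-pack
  # signature: same drug, instructions and dates)
  meds <- active_medications(st)
  row <- meds[meds$resident_id == tgt, ][1, ]
  dup_fields <- c("resident_id", "home_id", "vendor", "vendor_med_id",
                  "med_name", "instructions", "date_started", "mpuu_id",
                  "atc_code", "class", "prn", "daily_dose_mg",
                  "quantity_supplied")
  vals <- vapply(dup_fields, function(f) {
    v <- row[[f]]
    if (is.na(v)) NA_character_ else as.character(v)
  }, "")
  vals[1] <- src
  st2 <- apply_correction(st, log_entry(
    "P3_inhome", "champion_nurse", "add", "medication", "acopy1",
    sedetl:::fc(dup_fields, NA, vals)))
  before <- sum(active_medications(st2)$resident_id %in% c(src, tgt))
  st3 <- merge_residents(st2, src, tgt)
  after <- active_medications(st3)
  expect_equal(sum(after$resident_id == tgt), before - 1L)
  # exactly one of the pair survives: the one with the smallest med_id
  pair <- c(row$med_id, "acopy1")
  expect_equal(sum(pair %in% after$med_id), 1L)
  expect_true(min(pair) %in% after$med_id)
})

test_that("two distinct unmapped drugs with equal schedules never collapse", {
  st <- mini_state()
  prop <- propose_duplicates(st)
  src <- prop$source; tgt <- prop$target
  mk_add <- function(id, code, rid) log_entry(
    "P3_inhome", "champion_nurse", "add", "medication", id,
    sedetl:::fc(c("resident_id", "vendor", "vendor_med_id", "med_name",
                  "instructions", "date_started", "class"),
                NA, c(rid, "alpha_pack", code, paste("unknown", code),
                      "One tablet mane", "2015-05-01", "PENDING")))
  st2 <- apply_correction(st, mk_add("u1", "XA", src))
  st2 <- apply_correction(st2, mk_add("u2", "XB", tgt))
  st3 <- merge_residents(st2, src, tgt)
  expect_true(all(c("u1", "u2") %in% active_medications(st3)$med_id))
})

test_that("flag_suspects recomputes each reason with strict range bounds", {
  st <- mini_state()
  flags <- flag_suspects(st)
  zz_id <- st$medications$med_id[st$medications$vendor_med_id == "ZZ9999"]
  expect_true(any(flags$entity_id == zz_id &
                    flags$reason == "unmapped_medication"))
  # missing quantity on a sedative
  dia_id <- st$medications$med_id[
    st$medications$vendor_med_id == code_of("diazepam")]
  st2 <- apply_correction(st, log_entry(
    "P2_offsite", "project_staff", "modify", "medication", dia_id,
    sedetl:::fc("quantity_supplied", 28, NA)))
  expect_true(any(flag_suspects(st2)$reason == "missing_dose_quantity"))
  # unparseable / missing instructions
  st3 <- apply_correction(st, log_entry(
    "P2_offsite", "project_staff", "modify", "medication", dia_id,
    sedetl:::fc("parse_status", "parsed", "unparseable")))
  expect_true(any(flag_suspects(st3)$reason == "unparseable_instructions"))
  st4 <- apply_correction(st, log_entry(
    "P2_offsite", "project_staff", "modify", "medication", dia_id,
    sedetl:::fc("parse_status", "parsed", "missing")))
  expect_true(any(flag_suspects(st4)$reason == "missing_field"))
  # dose range: flag strictly above R x DDD and at exactly zero, not at the
  # boundary (diazepam DDD 10 mg, R = 4 -> limit 40 mg/day)
  at_limit <- apply_correction(st, log_entry(
    "P2_offsite", "project_staff", "modify", "medication", dia_id,
    sedetl:::fc("daily_dose_mg", 5, 40)))
  expect_false(any(flag_suspects(at_limit)$reason == "dose_out_of_range"))
  above <- apply_correction(st, log_entry(
    "P2_offsite", "project_staff", "modify", "medication", dia_id,
    sedetl:::fc("daily_dose_mg", 5, 40.5)))
  expect_true(any(flag_suspects(above)$reason == "dose_out_of_range"))
  zero <- apply_correction(st, log_entry(
    "P2_offsite", "project_staff", "modify", "medication", dia_id,
    sedetl:::fc("daily_dose_mg", 5, 0)))
  expect_true(any(flag_suspects(zero)$reason == "dose_out_of_range"))
  # non-sedatives are never range-flagged
  expect_false(any(flags$entity_id %in% st$medications$med_id[
    st$medications$class == "NONE"]))
})

test_that("verification requires every check and no blocking flags", {
  st <- mini_state()
  expect_equal(as.character(verify_home(st, "H01")), "NOT_VERIFIED")
  # resolve the unmapped code (a blocking flag), then check all residents
  cat <- fixture_catalogue()
  st <- apply_correction(st, log_entry(
    "P1_mapping", "research_pharmacist", "add", "mapping",
    "alpha_pack:ZZ9999",
    sedetl:::fc(c("target_concept_id", "origin"), NA,
                c(as.character(cat$tpuu1_id[cat$drug == "nitrazepam"]),
                  "manual"))))
  for (rid in active_residents(st)$resident_id)
    st <- mark_checked(st, rid)
  v <- verify_home(st, "H01")
  expect_equal(as.character(v), "VERIFIED")
  expect_length(attr(v, "reasons"), 0)
  # a blocking flag re-locks the home; advisory flags do not
  dia_id <- st$medications$med_id[
    st$medications$vendor_med_id == code_of("diazepam")]
  blocked <- apply_correction(st, log_entry(
    "P2_offsite", "project_staff", "modify", "medication", dia_id,
    sedetl:::fc("quantity_supplied", 28, NA)))
  expect_equal(as.character(verify_home(blocked, "H01")), "NOT_VERIFIED")
  advisory <- apply_correction(st, log_entry(
    "P2_offsite", "project_staff", "modify", "medication", dia_id,
    sedetl:::fc("daily_dose_mg", 5, 999)))
  expect_equal(as.character(verify_home(advisory, "H01")), "VERIFIED")
})

test_that("replay reproduces the live state and rejects gapped logs", {
  st0 <- mini_state()
  st <- st0
  cat <- fixture_catalogue()
  st <- apply_correction(st, log_entry(
    "P1_mapping", "research_pharmacist", "add", "mapping",
    "alpha_pack:ZZ9999",
    sedetl:::fc(c("target_concept_id", "origin"), NA,
                c(as.character(cat$tpuu1_id[cat$drug == "nitrazepam"]),
                  "manual"))))
  st <- apply_correction(st, log_entry(
    "P2_offsite", "project_staff", "modify", "medication",
    st$medications$med_id[1], sedetl:::fc("quantity_supplied", 28, 56)))
  prop <- propose_duplicates(st)
  st <- merge_residents(st, prop$source[1], prop$target[1])
  for (rid in active_residents(st)$resident_id) st <- mark_checked(st, rid)
  st <- apply_correction(st, log_entry(
    "P2_offsite", "project_staff", "delete", "resident",
    active_residents(st)$resident_id[1]))

  rep <- replay(st0, st$log)
  expect_equal(rep$residents, st$residents)
  expect_equal(rep$medications, st$medications)
  expect_equal(rep$bundle$vendor_map, st$bundle$vendor_map)
  expect_equal(rep$log[names(rep$log) != "field_changes"],
               st$log[names(st$log) != "field_changes"])

  gapped <- st$log[-2, , drop = FALSE]
  expect_error(replay(st0, gapped), class = "sedetl_log_error")
  shuffled <- st$log[rev(seq_len(nrow(st$log))), , drop = FALSE]
  expect_error(replay(st0, shuffled), class = "sedetl_log_error")
})

test_that("the transaction log round-trips through JSON lines", {
  st0 <- mini_state()
  st <- apply_correction(st0, log_entry(
    "P2_offsite", "project_staff", "modify", "medication",
    st0$medications$med_id[1], sedetl:::fc("quantity_supplied", 28, 56)))
  st <- apply_correction(st, log_entry(
    "P2_offsite", "project_staff", "delete", "medication",
    st$medications$med_id[2]))
  p <- tempfile(fileext = ".jsonl")
  write_log_jsonl(st$log, p)
  log2 <- read_log_jsonl(p)
  expect_equal(log2$seq, st$log$seq)
  expect_equal(log2$entity_id, st$log$entity_id)
  expect_equal(log2$field_changes[[1]], st$log$field_changes[[1]])
  rep <- replay(st0, log2)
  expect_equal(rep$medications, st$medications)
  unlink(p)
})

test_that("correction statistics count human entries per phase", {
  stats <- correction_stats(c(P1_mapping = 219, P2_offsite = 764,
                              P3_inhome = 1870, P4_retrospective = 961))
  expect_equal(stats$pct, c(5.74, 20.03, 49.03, 25.20))
  expect_equal(sum(stats$n), 3814L)

  st <- mini_state()
  dia_id <- st$medications$med_id[
    st$medications$vendor_med_id == code_of("diazepam")]
  st <- apply_correction(st, log_entry(
    "P2_offsite", "project_staff", "modify", "medication", dia_id,
    sedetl:::fc("quantity_supplied", 28, 56)))
  rid <- active_residents(st)$resident_id[1]
  st <- mark_checked(st, rid)
  st <- apply_correction(st, log_entry(
    "P2_offsite", "project_staff", "delete", "resident", rid))
  from_log <- correction_stats(st$log)
  # cascade deletes are system entries and must not count
  expect_equal(from_log$n[from_log$phase == "P2_offsite"], 2L)
  expect_equal(from_log$n[from_log$phase == "P3_inhome"], 1L)
  expect_equal(sum(from_log$n), 3L)
  filt <- correction_stats(st$log, known_error_filter = function(row)
    row$action == "delete")
  expect_equal(sum(filt$n_excl), 2L)
  expect_equal(filt$pct_excl[filt$phase == "P2_offsite"], 50)
})

test_that("manual entry uses the same machinery and warns on non-sedatives", {
  st <- mini_state()
  rid <- active_residents(st)$resident_id[1]
  entries <- list(log_entry(
    "P3_inhome", "champion_nurse", "add", "medication", "man001",
    sedetl:::fc(c("resident_id", "class", "prn", "daily_dose_mg"),
                NA, c(rid, "BENZODIAZEPINE", FALSE, 5))))
  st2 <- manual_entry_session(st, entries)
  expect_equal(st2$log$phase, "manual_entry")
  expect_true("man001" %in% active_medications(st2)$med_id)
  nonsed <- list(log_entry(
    "P3_inhome", "champion_nurse", "add", "medication", "man002",
    sedetl:::fc(c("resident_id", "class"), NA, c(rid, "NONE"))))
  expect_warning(manual_entry_session(st, nonsed), "not a sedative")
  # prepopulation copies a prior state's records
  st3 <- manual_entry_session(mini_state(), list(), prepopulate_from = st2)
  expect_true("man001" %in% st3$medications$med_id)
})
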