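# Four-phase validation / verification workflow over an append-only
# transaction log.
#
#   P1_mapping        unmapped-medication resolution (research pharmacist)
#   P2_offsite        off-site validation of obvious errors (project staff)
#   P3_inhome         in-home verification by the champion nurse
#   P4_retrospective  retrospective cleaning, mainly duplicate-profile merges
#
# State is event-sourced: a pure function of (initial snapshot, log). Every
# add / modify / delete / merge is a log entry; cascades (e.g. deleting a
# departed resident excludes their medications) are recorded as
# system-generated entries, so replaying the full log over the initial state
# reproduces the live state exactly.

PHASES <- c("P1_mapping", "P2_offsite", "P3_inhome", "P4_retrospective",
            "ingest", "manual_entry")
ACTOR_ROLES <- c("system", "research_pharmacist", "project_staff",
                 "champion_nurse")
ACTIONS <- c("add", "modify", "delete", "merge")
ENTITY_KINDS <- c("resident", "medication", "mapping")

empty_log <- function() {
  data.frame(seq = integer(), phase = character(), actor_role = character(),
             action = character(), entity_kind = character(),
             entity_id = character(), timestamp = character(),
             field_changes = I(list()), stringsAsFactors = FALSE)
}

#' Create a transaction log entry
#'
#' @param phase one of the workflow phases.
#' @param actor_role who made the change.
#' @param action `"add"`, `"modify"`, `"delete"` or `"merge"`.
#' @param entity_kind `"resident"`, `"medication"` or `"mapping"`.
#' @param entity_id identifier of the affected entity (for merges, the source
#'   resident; the target is carried in `field_changes`).
#' @param field_changes data frame with columns `field`, `old`, `new`
#'   (character); required non-empty for modifies.
#' @param timestamp ISO 8601 timestamp string.
#' @return a `sedetl_log_entry` list (without a `seq`; sequence numbers are
#'   assigned when the entry is applied).
#' @export
log_entry <- function(phase, actor_role, action, entity_kind, entity_id,
                      field_changes = NULL, timestamp = "1970-01-01T00:00:00") {
  stopifnot(phase %in% PHASES, actor_role %in% ACTOR_ROLES,
            action %in% ACTIONS, entity_kind %in% ENTITY_KINDS)
  if (action == "modify" &&
      (is.null(field_changes) || nrow(field_changes) < 1))
    stop_contract("modify entries must carry at least one field change")
  structure(list(phase = phase, actor_role = actor_role, action = action,
                 entity_kind = entity_kind, entity_id = as.character(entity_id),
                 field_changes = field_changes %||%
                   data.frame(field = character(), old = character(),
                              new = character(), stringsAsFactors = FALSE),
                 timestamp = timestamp),
            class = "sedetl_log_entry")
}

fc <- function(field, old, new) {
  data.frame(field = field,
             old = vapply(old, as_chr, ""),
             new = vapply(new, as_chr, ""),
             stringsAsFactors = FALSE)
}

#' Build a working state from an enriched snapshot
#'
#' @param snapshot an enriched `sedetl_snapshot` (see [enrich_snapshot()]).
#' @param bundle the terminology bundle used for enrichment.
#' @param config optional named list of thresholds (e.g. `ddd_range_multiple`).
#' @return an object of class `sedetl_state`.
#' @export
new_state <- function(snapshot, bundle, config = list()) {
  res <- snapshot$residents
  res$checked <- FALSE
  res$deleted <- FALSE
  meds <- snapshot$medications
  meds$deleted <- FALSE
  structure(list(
    snapshot_label = snapshot$snapshot_label,
    timestamp = snapshot$timestamp,
    home_ids = snapshot$home_ids,
    residents = res,
    medications = meds,
    bundle = bundle,
    log = empty_log(),
    config = utils::modifyList(list(ddd_range_multiple = 4), config)
  ), class = "sedetl_state")
}

#' Current (non-deleted, non-merged) residents
#' @param state a `sedetl_state`.
#' @return data frame of active resident profiles.
#' @export
active_residents <- function(state) {
  r <- state$residents
  r[!r$deleted & is.na(r$merged_into), , drop = FALSE]
}

#' Current (non-deleted) medication records
#' @param state a `sedetl_state`.
#' @return data frame of active medication records.
#' @export
active_medications <- function(state) {
  m <- state$medications
  m[!m$deleted, , drop = FALSE]
}

# typed column sets for reconstructing rows from field changes
MED_NUMERIC <- c("mpuu_id", "daily_dose_mg", "units_per_administration",
                 "administrations_per_day")
MED_INTEGER <- c("quantity_supplied")
LOGICAL_FIELDS <- c("prn", "deleted", "checked")

coerce_field <- function(field, value) {
  if (field %in% MED_NUMERIC) as.numeric(value)
  else if (field %in% MED_INTEGER) as.integer(value)
  else if (field %in% LOGICAL_FIELDS) as.logical(value)
  else as.character(value)
}

# pure application of one entry; generates no new entries, so it is the
# replay primitive
apply_entry <- function(state, entry) {
  kind <- entry$entity_kind
  id <- entry$entity_id
  if (kind == "mapping") {
    if (entry$action != "add")
      stop_contract("only 'add' is supported for mapping entries")
    chg <- stats::setNames(entry$field_changes$new, entry$field_changes$field)
    vc <- strsplit(id, ":", fixed = TRUE)[[1]]
    state$bundle <- add_manual_mapping(
      state$bundle, vc[1], paste(vc[-1], collapse = ":"),
      as.numeric(chg[["target_concept_id"]]),
      equivalent_of_name =
        if (identical(unname(chg["origin"]), "equivalent_fallback"))
          unname(chg["equivalent_of_name"]) %||% "equivalent" else NULL)
    # re-enrich records of the newly mapped code
    state <- reenrich_code(state, vc[1], paste(vc[-1], collapse = ":"))
    return(state)
  }

  tbl <- if (kind == "resident") "residents" else "medications"
  df <- state[[tbl]]
  idcol <- if (kind == "resident") "resident_id" else "med_id"
  row_idx <- which(df[[idcol]] == id)

  if (entry$action == "add") {
    if (length(row_idx))
      stop_integrity(sprintf("%s %s already exists", kind, id))
    new_row <- df[0, , drop = FALSE][1, , drop = FALSE]
    new_row[[idcol]] <- id
    for (j in seq_len(nrow(entry$field_changes))) {
      f <- entry$field_changes$field[j]
      if (!f %in% names(df)) next
      new_row[[f]] <- coerce_field(f, entry$field_changes$new[j])
    }
    if (is.na(new_row$deleted)) new_row$deleted <- FALSE
    if (kind == "resident" && is.na(new_row$checked)) new_row$checked <- FALSE
    if (kind == "medication") {
      if (!new_row$resident_id %in% state$residents$resident_id)
        stop_integrity(sprintf(
          "medication %s references unknown resident %s", id,
          new_row$resident_id))
    }
    state[[tbl]] <- rbind(df, new_row)
    rownames(state[[tbl]]) <- NULL
    return(state)
  }

  if (!length(row_idx))
    stop_integrity(sprintf("%s %s does not exist", kind, id))

  if (entry$action == "modify") {
    for (j in seq_len(nrow(entry$field_changes))) {
      f <- entry$field_changes$field[j]
      if (!f %in% names(df))
        stop_integrity(sprintf("unknown field '%s' on %s", f, kind))
      df[row_idx, f] <- coerce_field(f, entry$field_changes$new[j])
    }
    state[[tbl]] <- df
    return(state)
  }

  if (entry$action == "delete") {
    df$deleted[row_idx] <- TRUE
    state[[tbl]] <- df
    return(state)
  }

  if (entry$action == "merge") {
    if (kind != "resident") stop_contract("merge applies to residents only")
    chg <- stats::setNames(entry$field_changes$new, entry$field_changes$field)
    target <- unname(chg[["merged_into"]])
    state <- apply_merge(state, id, target)
    return(state)
  }
  stop_contract(sprintf("unknown action '%s'", entry$action))
}

apply_merge <- function(state, source_id, target_id) {
  res <- state$residents
  if (!target_id %in% res$resident_id)
    stop_integrity(sprintf("merge target %s does not exist", target_id))
  meds <- state$medications
  move <- !meds$deleted & meds$resident_id == source_id
  meds$resident_id[move] <- target_id
  # collapse exact duplicates (same MPUU, same schedule, same dates) to one,
  # keeping the earliest med_id; deterministic so replay agrees
  act <- which(!meds$deleted & meds$resident_id == target_id)
  act <- act[order(meds$med_id[act])]
  # unresolved rows have no MPUU; their vendor code stands in so two
  # distinct unmapped drugs with identical schedules never collapse
  drug_key <- ifelse(is.na(meds$mpuu_id[act]),
                     paste0("code:", meds$vendor[act], ":",
                            meds$vendor_med_id[act]),
                     as.character(meds$mpuu_id[act]))
  sig <- paste(drug_key, meds$instructions[act],
               meds$date_started[act], meds$date_ceased[act], sep = "\r")
  dup <- duplicated(sig)
  meds$deleted[act[dup]] <- TRUE
  res$merged_into[res$resident_id == source_id] <- target_id
  state$medications <- meds
  state$residents <- res
  state
}

# after a manual mapping lands, records of that vendor code pick up MPUU,
# ATC, class and dose
reenrich_code <- function(state, vendor, vendor_code) {
  meds <- state$medications
  sel <- which(!meds$deleted & meds$vendor == vendor &
                 meds$vendor_med_id == vendor_code & is.na(meds$mpuu_id))
  if (!length(sel)) return(state)
  mpuu <- resolve_to_mpuu(vendor, vendor_code, state$bundle)
  if (is.na(mpuu)) return(state)
  codes <- atc_codes_for_mpuu(mpuu, state$bundle)
  meds$mpuu_id[sel] <- mpuu
  if (length(codes)) {
    all_cls <- classify_atc(codes)
    sed_i <- which(all_cls != "NONE")
    pick <- if (length(sed_i)) sed_i[1] else 1L
    meds$atc_code[sel] <- codes[[pick]]
    meds$class[sel] <- if (length(sed_i)) all_cls[[pick]] else "NONE"
  }
  strength <- mpuu_strengths(rep(mpuu, length(sel)), state$bundle)
  parsed <- meds$parse_status[sel] == "parsed"
  meds$daily_dose_mg[sel] <- ifelse(
    parsed & !is.na(strength),
    meds$units_per_administration[sel] * meds$administrations_per_day[sel] *
      strength, NA_real_)
  state$medications <- meds
  state
}

#' Apply a correction entry to the state
#'
#' Validates the entry, applies it, and appends it (plus any system-generated
#' cascade entries) to the transaction log. Deleting a resident cascades to
#' all of their active medications, each cascade recorded as a
#' system-authored delete entry. The input state is never mutated.
#'
#' @param state a `sedetl_state`.
#' @param entry a `sedetl_log_entry` (see [log_entry()]).
#' @return the new state.
#' @export
apply_correction <- function(state, entry) {
  entries <- list(entry)
  if (entry$action == "delete" && entry$entity_kind == "resident") {
    meds <- active_medications(state)
    casc <- meds$med_id[meds$resident_id == entry$entity_id]
    entries <- c(entries, lapply(casc, function(mid)
      log_entry(entry$phase, "system", "delete", "medication", mid,
                timestamp = entry$timestamp)))
  }
  for (e in entries) {
    state <- apply_entry(state, e)
    state$log <- append_log(state$log, e)
  }
  state
}

append_log <- function(log, entry) {
  row <- data.frame(seq = nrow(log) + 1L, phase = entry$phase,
                    actor_role = entry$actor_role, action = entry$action,
                    entity_kind = entry$entity_kind, entity_id = entry$entity_id,
                    timestamp = entry$timestamp,
                    stringsAsFactors = FALSE)
  row$field_changes <- I(list(entry$field_changes))
  rbind(log, row)
}

#' Merge a duplicate resident profile into another
#'
#' Reassigns the source profile's medications to the target, collapses exact
#' duplicate medication rows (same MPUU, schedule and dates — the split-pack
#' signature), marks the source as merged, and logs the merge. Merging across
#' homes is refused unless explicitly overridden.
#'
#' @param state a `sedetl_state`.
#' @param source_id resident id to merge away.
#' @param target_id resident id that absorbs the records.
#' @param phase workflow phase (normally `"P4_retrospective"`).
#' @param actor_role defaults to `"project_staff"`.
#' @param allow_cross_home set `TRUE` to permit a cross-home merge.
#' @param timestamp entry timestamp.
#' @return the new state.
#' @export
merge_residents <- function(state, source_id, target_id,
                            phase = "P4_retrospective",
                            actor_role = "project_staff",
                            allow_cross_home = FALSE,
                            timestamp = "1970-01-01T00:00:00") {
  res <- state$residents
  src <- res[res$resident_id == source_id, , drop = FALSE]
  tgt <- res[res$resident_id == target_id, , drop = FALSE]
  if (!nrow(src) || !nrow(tgt))
    stop_integrity("merge source or target does not exist")
  if (source_id == target_id)
    stop_contract("cannot merge a resident into itself")
  if (!is.na(tgt$merged_into))
    stop_contract("merge target is itself merged; choose the surviving profile")
  if (src$home_id != tgt$home_id && !allow_cross_home)
    stop_conflict(sprintf(
      "refusing cross-home merge (%s -> %s); set allow_cross_home = TRUE",
      src$home_id, tgt$home_id))
  entry <- log_entry(phase, actor_role, "merge", "resident", source_id,
                     fc("merged_into", NA, target_id), timestamp)
  apply_correction(state, entry)
}

#' Propose duplicate resident profiles
#'
#' Conservative by default: proposes pairs whose normalized identity keys
#' (pseudonym of normalized name + birth date) collide — the split-pack /
#' re-entry signature. With `fuzzy = TRUE`, also proposes pairs in the same
#' home whose display tokens match at the configured string distance. For a
#' k-way collision, the lexicographically first profile is the proposed
#' target for each of the others. Proposals only; merges require
#' [merge_residents()].
#'
#' @param state a `sedetl_state` (or snapshot with residents).
#' @param fuzzy opt in to approximate matching.
#' @param max_distance maximum string distance for fuzzy display-token match.
#' @return data frame `source`, `target`, `score` (1 for exact identity-key
#'   collision), ranked by descending score.
#' @export
propose_duplicates <- function(state, fuzzy = FALSE, max_distance = 1) {
  res <- if (inherits(state, "sedetl_state")) active_residents(state)
         else state$residents
  out <- data.frame(source = character(), target = character(),
                    score = numeric(), stringsAsFactors = FALSE)
  split_keys <- split(res$resident_id, res$identity_key)
  for (ids in split_keys) {
    if (length(ids) < 2) next
    ids <- sort(ids)
    out <- rbind(out, data.frame(source = ids[-1], target = ids[1],
                                 score = 1, stringsAsFactors = FALSE))
  }
  if (fuzzy) {
    for (h in unique(res$home_id)) {
      rh <- res[res$home_id == h, , drop = FALSE]
      if (nrow(rh) < 2) next
      d <- utils::adist(rh$display_token)
      idx <- which(d <= max_distance & upper.tri(d), arr.ind = TRUE)
      for (k in seq_len(nrow(idx))) {
        a <- rh$resident_id[idx[k, 1]]; b <- rh$resident_id[idx[k, 2]]
        pair <- sort(c(a, b))
        if (rh$identity_key[idx[k, 1]] == rh$identity_key[idx[k, 2]]) next
        out <- rbind(out, data.frame(source = pair[2], target = pair[1],
                                     score = 1 - d[idx[k, 1], idx[k, 2]] /
                                       (max_distance + 1),
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out <- out[!duplicated(out[c("source", "target")]), , drop = FALSE]
  out[order(-out$score, out$source), , drop = FALSE]
}

#' Flag missing or suspect medication data
#'
#' Recomputes (never stores) review flags over active sedative records:
#' missing packed quantity, unparseable instructions, missing instruction
#' text, daily dose outside the typical range (strictly above `R` times the
#' drug's DDD, or exactly zero), and unresolved terminology mapping.
#'
#' @param state a `sedetl_state`.
#' @param ddd_table DDD reference table (defaults to the bundle's).
#' @param range_multiple the typical-range multiple `R` (default from state
#'   config, 4).
#' @return data frame `entity_id`, `reason`, `detail`.
#' @export
flag_suspects <- function(state, ddd_table = NULL, range_multiple = NULL) {
  ddd_table <- ddd_table %||% state$bundle$ddd
  R <- range_multiple %||% state$config$ddd_range_multiple
  meds <- active_medications(state)
  sed <- meds[meds$class %in% c("BENZODIAZEPINE", "ANTIPSYCHOTIC", "PENDING"), ,
              drop = FALSE]
  flags <- list()
  add_flag <- function(ids, reason, detail) {
    if (length(ids))
      flags[[length(flags) + 1L]] <<- data.frame(
        entity_id = ids, reason = reason, detail = detail,
        stringsAsFactors = FALSE)
  }
  add_flag(sed$med_id[sed$class == "PENDING"], "unmapped_medication",
           "no terminology mapping for vendor code")
  real_sed <- sed[sed$class != "PENDING", , drop = FALSE]
  add_flag(real_sed$med_id[is.na(real_sed$quantity_supplied)],
           "missing_dose_quantity", "quantity_supplied absent")
  add_flag(real_sed$med_id[real_sed$parse_status == "unparseable"],
           "unparseable_instructions", "instructions outside dose grammar")
  add_flag(real_sed$med_id[real_sed$parse_status == "missing"],
           "missing_field", "instructions absent")
  dosed <- real_sed[!is.na(real_sed$daily_dose_mg) &
                      !is.na(real_sed$atc_code) &
                      real_sed$atc_code %in% ddd_table$atc_code, , drop = FALSE]
  if (nrow(dosed)) {
    lim <- R * ddd_value_for(dosed$atc_code, ddd_table)
    out_of_range <- dosed$daily_dose_mg > lim | dosed$daily_dose_mg == 0
    add_flag(dosed$med_id[out_of_range], "dose_out_of_range",
             sprintf("daily dose %.3g mg vs limit %.3g mg",
                     dosed$daily_dose_mg[out_of_range], lim[out_of_range]))
  }
  if (!length(flags))
    return(data.frame(entity_id = character(), reason = character(),
                      detail = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}

#' Mark a resident's records as checked by the champion nurse
#'
#' @param state a `sedetl_state`.
#' @param resident_id resident to mark.
#' @param actor_role defaults to `"champion_nurse"`.
#' @param timestamp entry timestamp.
#' @return the new state.
#' @export
mark_checked <- function(state, resident_id, actor_role = "champion_nurse",
                         timestamp = "1970-01-01T00:00:00") {
  apply_correction(state, log_entry(
    "P3_inhome", actor_role, "modify", "resident", resident_id,
    fc("checked", "FALSE", "TRUE"), timestamp))
}

#' Verification status of a home
#'
#' A home is `VERIFIED` when every active resident has been explicitly marked
#' checked during in-home verification and no blocking flags remain on its
#' sedative records (a missing packed quantity or an unresolved terminology
#' mapping blocks; other flags are advisory). Audit report generation is
#' gated on this status.
#'
#' @param state a `sedetl_state`.
#' @param home_id home to check.
#' @return `"VERIFIED"` or `"NOT_VERIFIED"`, with attribute `"reasons"`.
#' @export
verify_home <- function(state, home_id) {
  res <- active_residents(state)
  res <- res[res$home_id == home_id, , drop = FALSE]
  reasons <- character()
  if (any(!res$checked))
    reasons <- c(reasons, sprintf("%d resident(s) not yet checked",
                                  sum(!res$checked)))
  flags <- flag_suspects(state)
  meds <- active_medications(state)
  home_meds <- meds$med_id[meds$home_id == home_id]
  blocking <- flags[flags$entity_id %in% home_meds &
                      flags$reason %in% c("missing_dose_quantity",
                                          "unmapped_medication"), ,
                    drop = FALSE]
  if (nrow(blocking))
    reasons <- c(reasons, sprintf("%d blocking flag(s) on sedative records",
                                  nrow(blocking)))
  status <- if (length(reasons)) "NOT_VERIFIED" else "VERIFIED"
  structure(status, reasons = reasons)
}

#' Deterministically replay a transaction log
#'
#' Folds the log over the initial state with the same pure application used
#' live; the result equals the live final state exactly. The log must be
#' gap-free and strictly ordered by `seq`.
#'
#' @param initial_state the state before any logged correction.
#' @param log a transaction log data frame (as in `state$log`).
#' @return the reconstructed state.
#' @export
replay <- function(initial_state, log) {
  if (nrow(log) && !identical(as.integer(log$seq), seq_len(nrow(log))))
    stop_sedetl("transaction log has a gap or reordering in seq",
                "sedetl_log_error")
  state <- initial_state
  for (i in seq_len(nrow(log))) {
    entry <- log_entry(log$phase[i], log$actor_role[i], log$action[i],
                       log$entity_kind[i], log$entity_id[i],
                       field_changes = log$field_changes[[i]],
                       timestamp = log$timestamp[i])
    state <- apply_entry(state, entry)
    state$log <- append_log(state$log, entry)
  }
  state
}

#' Write / read a transaction log as JSON lines
#'
#' One JSON object per line, append-only on disk.
#'
#' @param log transaction log data frame.
#' @param path file path.
#' @return `path` (write) or the log data frame (read).
#' @export
write_log_jsonl <- function(log, path) {
  lines <- vapply(seq_len(nrow(log)), function(i) {
    jsonlite::toJSON(list(
      seq = log$seq[i], phase = log$phase[i], actor_role = log$actor_role[i],
      action = log$action[i], entity_kind = log$entity_kind[i],
      entity_id = log$entity_id[i], timestamp = log$timestamp[i],
      field_changes = log$field_changes[[i]]), auto_unbox = TRUE, na = "null")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_log_jsonl
#' @export
read_log_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  log <- empty_log()
  for (ln in lines) {
    x <- jsonlite::fromJSON(ln)
    fcs <- x$field_changes
    if (is.null(fcs) || !length(fcs))
      fcs <- data.frame(field = character(), old = character(),
                        new = character(), stringsAsFactors = FALSE)
    fcs$old <- as.character(fcs$old); fcs$new <- as.character(fcs$new)
    log <- append_log(log, log_entry(x$phase, x$actor_role, x$action,
                                     x$entity_kind, x$entity_id, fcs,
                                     x$timestamp))
  }
  log
}

#' Per-phase correction statistics
#'
#' Counts human-authored corrections (log entries whose actor is not the
#' system) per workflow phase, with percentages of the total; when a
#' known-error predicate is supplied, a second pair of columns reports the
#' same accounting with matching entries excluded, mirroring the two-column
#' breakdown used when systematic extraction faults are set aside.
#'
#' `log` may instead be a named numeric vector of per-phase counts, in which
#' case only percentages are computed from those counts.
#'
#' @param log transaction log data frame, or named per-phase count vector.
#' @param known_error_filter optional predicate taking one log row (as a
#'   list) and returning `TRUE` when the entry corrects a known systematic
#'   error.
#' @return data frame `phase`, `n`, `pct` (and `n_excl`, `pct_excl` when a
#'   filter is given); percentages at 2 decimal places, half away from zero.
#' @export
correction_stats <- function(log, known_error_filter = NULL) {
  core_phases <- PHASES[1:4]
  if (is.numeric(log)) {
    counts <- log
    phases <- names(counts) %||% core_phases[seq_along(counts)]
    return(data.frame(phase = phases, n = as.integer(counts),
                      pct = pct(counts, sum(counts)),
                      stringsAsFactors = FALSE, row.names = NULL))
  }
  corr <- log[log$actor_role != "system", , drop = FALSE]
  counts <- vapply(core_phases, function(p) sum(corr$phase == p), 0L)
  out <- data.frame(phase = core_phases, n = counts,
                    pct = pct(counts, sum(counts)),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(known_error_filter)) {
    keep <- !vapply(seq_len(nrow(corr)), function(i)
      isTRUE(known_error_filter(as.list(corr[i, ]))), logical(1))
    kept <- corr[keep, , drop = FALSE]
    n_excl <- vapply(core_phases, function(p) sum(kept$phase == p), 0L)
    out$n_excl <- n_excl
    out$pct_excl <- pct(n_excl, sum(n_excl))
  }
  out
}

#' Manual data entry session
#'
#' The fallback path when automated extraction is impossible: sedative
#' medications (and residents) are entered through the same enrichment
#' machinery as uploads, so entered records have an identical downstream
#' shape. Snapshots after the first can prepopulate from a prior state and
#' apply only the deltas. Entering a non-sedative medication in manual mode
#' is accepted with a warning (only sedatives are required in this mode).
#'
#' @param state the state to enter into; when `prepopulate_from` is given,
#'   its active residents and medications are copied first.
#' @param entries list of `sedetl_log_entry` objects (adds / modifies /
#'   deletes); each is applied with phase `"manual_entry"`.
#' @param prepopulate_from optional prior `sedetl_state`.
#' @return the new state.
#' @export
manual_entry_session <- function(state, entries, prepopulate_from = NULL) {
  if (!is.null(prepopulate_from)) {
    state$residents <- prepopulate_from$residents
    state$medications <- prepopulate_from$medications
  }
  for (e in entries) {
    e$phase <- "manual_entry"
    if (e$action == "add" && e$entity_kind == "medication") {
      cls <- e$field_changes$new[e$field_changes$field == "class"]
      if (length(cls) && !cls %in% c("BENZODIAZEPINE", "ANTIPSYCHOTIC"))
        warning(sprintf(
          "manual entry %s is not a sedative; accepted but flagged",
          e$entity_id), call. = FALSE)
    }
    state <- apply_correction(state, e)
  }
  state
}
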