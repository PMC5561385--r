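# Reading packing-system exports, pseudonymizing residents, linking pharmacy
# wing names to participating homes, and assembling point-in-time upload
# snapshots.
#
# Two plain-text export dialects stand in for the proprietary packing-system
# formats:
#   * table_export — a single sectioned file (the database-access style):
#       header line, then [residents], [medications] and [wings] tab-separated
#       tables, each with its own column header row.
#   * report — a flat file (the generated-report style): header line, then
#       repeated resident blocks, each a RES line followed by MED lines.
# Every file declares its dialect and vendor on the first line, e.g.
#   #sedetl-export<TAB>dialect=table_export<TAB>vendor=alpha_pack<TAB>version=1

MED_COLS <- c("vendor_med_id", "med_name", "instructions", "quantity_supplied",
              "date_started", "date_ceased", "prescriber", "resident_key",
              "wing_name")
RES_COLS <- c("resident_key", "name", "birth_date", "wing_name")

parse_export_header <- function(line) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (!length(fields) || fields[[1]] != "#sedetl-export")
    stop_format("file does not start with a '#sedetl-export' header line")
  kv <- strsplit(fields[-1], "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  if (!("dialect" %in% names(vals)))
    stop_format("export header does not declare a dialect")
  if (!vals[["dialect"]] %in% c("table_export", "report"))
    stop_format(sprintf("unsupported packing-system export dialect '%s'",
                        vals[["dialect"]]))
  as.list(vals)
}

#' Read a packing-system export file
#'
#' Parses either export dialect into raw medication rows and raw resident
#' rows. Malformed lines are never dropped silently: they are returned in a
#' reject table with their line numbers and a reason.
#'
#' @param path path to an export file.
#' @param dialect optional dialect name; when given it must match the file's
#'   declared dialect.
#' @return a list with elements `rows` (raw medication rows), `residents`,
#'   `rejects` (line, reason, content), `vendor` and `dialect`.
#' @export
read_export <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop_format(sprintf("export file not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines)) stop_format("empty export file (no header line)")
  hdr <- parse_export_header(lines[[1]])
  if (!is.null(dialect) && !identical(dialect, hdr$dialect))
    stop_format(sprintf("expected dialect '%s' but file declares '%s'",
                        dialect, hdr$dialect))
  body <- lines[-1]
  out <- switch(hdr$dialect,
                table_export = parse_table_export(body),
                report = parse_report(body))
  out$vendor <- hdr$vendor %||% NA_character_
  out$dialect <- hdr$dialect
  if (nrow(out$rows)) out$rows$vendor <- out$vendor
  out$rows <- normalize_med_rows(out$rows, out)
  out
}

empty_meds <- function() {
  df <- as.data.frame(stats::setNames(rep(list(character()), length(MED_COLS)),
                                      MED_COLS), stringsAsFactors = FALSE)
  df$vendor <- character()
  df
}

empty_res <- function() {
  as.data.frame(stats::setNames(rep(list(character()), length(RES_COLS)),
                                RES_COLS), stringsAsFactors = FALSE)
}

empty_rejects <- function() {
  data.frame(line = integer(), reason = character(), content = character(),
             stringsAsFactors = FALSE)
}

# shared row-level validation; moves bad rows to the reject list
normalize_med_rows <- function(rows, out) {
  if (!nrow(rows)) return(rows)
  rows$quantity_supplied <- suppressWarnings(as.integer(rows$quantity_supplied))
  for (col in c("date_started", "date_ceased")) {
    bad_date <- !is.na(rows[[col]]) & rows[[col]] != "" &
      is.na(as.Date(rows[[col]], format = "%Y-%m-%d"))
    rows[[col]][rows[[col]] %in% ""] <- NA_character_
    if (any(bad_date)) rows[[col]][bad_date] <- NA_character_
  }
  rows
}

parse_table_export <- function(body) {
  section <- NA_character_
  header <- NULL
  rows <- list(residents = list(), medications = list(), wings = list())
  rejects <- empty_rejects()
  expected <- list(residents = RES_COLS, medications = MED_COLS[MED_COLS != "vendor"],
                   wings = c("wing_name"))
  for (i in seq_along(body)) {
    line <- body[[i]]
    if (line == "") next
    if (grepl("^\\[[a-z]+\\]$", line)) {
      section <- sub("^\\[([a-z]+)\\]$", "\\1", line)
      if (!section %in% names(rows))
        stop_format(sprintf("unknown section [%s] at line %d", section, i + 1))
      header <- NULL
      next
    }
    if (is.na(section)) {
      rejects <- rbind(rejects, data.frame(
        line = i + 1L, reason = "data before any section header",
        content = line, stringsAsFactors = FALSE))
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (is.null(header)) {
      header <- fields
      if (!all(expected[[section]] %in% header))
        stop_format(sprintf("section [%s] is missing required columns", section))
      next
    }
    length(fields) <- length(header)
    rec <- stats::setNames(as.list(fields), header)
    bad <- validate_record(rec, section)
    if (!is.null(bad)) {
      rejects <- rbind(rejects, data.frame(line = i + 1L, reason = bad,
                                           content = line,
                                           stringsAsFactors = FALSE))
    } else {
      rows[[section]][[length(rows[[section]]) + 1L]] <- rec
    }
  }
  list(rows = bind_records(rows$medications, MED_COLS),
       residents = bind_records(rows$residents, RES_COLS),
       wings = vapply(rows$wings, function(r) r$wing_name, ""),
       rejects = rejects)
}

parse_report <- function(body) {
  meds <- list(); res <- list(); rejects <- empty_rejects()
  cur_res <- NULL
  for (i in seq_along(body)) {
    line <- body[[i]]
    if (line == "") next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    tag <- fields[[1]]
    if (tag == "RES") {
      if (length(fields) < 5) {
        rejects <- rbind(rejects, data.frame(line = i + 1L,
          reason = "short RES line", content = line, stringsAsFactors = FALSE))
        cur_res <- NULL
        next
      }
      cur_res <- stats::setNames(as.list(fields[2:5]), RES_COLS)
      res[[length(res) + 1L]] <- cur_res
    } else if (tag == "MED") {
      if (is.null(cur_res)) {
        rejects <- rbind(rejects, data.frame(line = i + 1L,
          reason = "MED line before any RES line", content = line,
          stringsAsFactors = FALSE))
        next
      }
      vals <- fields[-1]
      length(vals) <- 7L
      rec <- stats::setNames(as.list(vals),
                             c("vendor_med_id", "med_name", "instructions",
                               "quantity_supplied", "date_started",
                               "date_ceased", "prescriber"))
      rec$resident_key <- cur_res$resident_key
      rec$wing_name <- cur_res$wing_name
      bad <- validate_record(rec, "medications")
      if (!is.null(bad)) {
        rejects <- rbind(rejects, data.frame(line = i + 1L, reason = bad,
                                             content = line,
                                             stringsAsFactors = FALSE))
      } else {
        meds[[length(meds) + 1L]] <- rec
      }
    } else {
      rejects <- rbind(rejects, data.frame(line = i + 1L,
        reason = sprintf("unknown record tag '%s'", tag), content = line,
        stringsAsFactors = FALSE))
    }
  }
  list(rows = bind_records(meds, MED_COLS),
       residents = bind_records(res, RES_COLS),
       wings = unique(vapply(res, function(r) r$wing_name, "")),
       rejects = rejects)
}

validate_record <- function(rec, section) {
  if (section == "medications") {
    if (is.na(rec$vendor_med_id %||% NA) || !nzchar(rec$vendor_med_id %||% ""))
      return("missing vendor_med_id")
    if (is.na(rec$med_name %||% NA) || !nzchar(rec$med_name %||% ""))
      return("missing med_name")
    ds <- rec$date_started %||% ""
    dc <- rec$date_ceased %||% ""
    if (nzchar(ds %||% "") && nzchar(dc %||% "") &&
        !is.na(as.Date(ds, "%Y-%m-%d")) && !is.na(as.Date(dc, "%Y-%m-%d")) &&
        as.Date(dc) < as.Date(ds))
      return("date_ceased before date_started")
  } else if (section == "residents") {
    if (is.na(rec$resident_key %||% NA) || !nzchar(rec$resident_key %||% ""))
      return("missing resident_key")
    if (is.na(rec$name %||% NA) || !nzchar(rec$name %||% ""))
      return("missing resident name")
  }
  NULL
}

bind_records <- function(recs, cols) {
  if (!length(recs)) {
    df <- as.data.frame(stats::setNames(rep(list(character()), length(cols)),
                                        cols), stringsAsFactors = FALSE)
    return(df)
  }
  df <- as.data.frame(stats::setNames(lapply(cols, function(cn) {
    vapply(recs, function(r) {
      v <- r[[cn]]
      if (is.null(v) || is.na(v) || !nzchar(v)) NA_character_ else v
    }, "")
  }), cols), stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Write an export file in either dialect
#'
#' Inverse of [read_export()]; used to render synthetic ground truth in both
#' dialects and to test round-trip fidelity.
#'
#' @param data list with `rows` (medication rows), `residents`, and optional
#'   `wings`; as produced by [read_export()] or the synthetic generator.
#' @param path output path.
#' @param dialect `"table_export"` or `"report"`.
#' @param vendor vendor name written into the header.
#' @return `path`, invisibly.
#' @export
write_export <- function(data, path, dialect, vendor) {
  stopifnot(dialect %in% c("table_export", "report"))
  fmt <- function(x) ifelse(is.na(x), "", as.character(x))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#sedetl-export\tdialect=%s\tvendor=%s\tversion=1",
                     dialect, vendor), con)
  res <- data$residents
  meds <- data$rows
  med_cols <- MED_COLS[MED_COLS != "vendor"]
  if (dialect == "table_export") {
    writeLines("[residents]", con)
    writeLines(paste(RES_COLS, collapse = "\t"), con)
    if (nrow(res))
      writeLines(apply(res[RES_COLS], 1, function(r) paste(fmt(r), collapse = "\t")), con)
    writeLines("[medications]", con)
    writeLines(paste(med_cols, collapse = "\t"), con)
    if (nrow(meds))
      writeLines(apply(meds[med_cols], 1, function(r) paste(fmt(r), collapse = "\t")), con)
    writeLines("[wings]", con)
    writeLines("wing_name", con)
    wings <- data$wings %||% character()
    if (!length(wings)) wings <- unique(res$wing_name)
    wings <- wings[!is.na(wings)]
    if (length(wings)) writeLines(as.character(wings), con)
  } else {
    ord <- c("vendor_med_id", "med_name", "instructions", "quantity_supplied",
             "date_started", "date_ceased", "prescriber")
    for (i in seq_len(nrow(res))) {
      writeLines(paste(c("RES", fmt(unlist(res[i, RES_COLS]))), collapse = "\t"), con)
      mine <- meds[meds$resident_key == res$resident_key[i], , drop = FALSE]
      if (nrow(mine))
        writeLines(apply(mine[ord], 1, function(r)
          paste(c("MED", fmt(r)), collapse = "\t")), con)
    }
  }
  invisible(path)
}

#' Assign pharmacy wing names to participating homes
#'
#' @param wing_names character vector of wing/home-group names seen in an
#'   export.
#' @param home_registry named list: `home_id -> character vector` of accepted
#'   wing names and aliases.
#' @return data frame with `wing_name` and `home_id` (`NA` when unassigned).
#'   A wing matching two homes is an ambiguity error requiring explicit
#'   configuration.
#' @export
link_wings <- function(wing_names, home_registry) {
  wing_names <- unique(wing_names[!is.na(wing_names)])
  assign_one <- function(w) {
    hits <- names(home_registry)[vapply(home_registry, function(al)
      tolower(w) %in% tolower(al), logical(1))]
    if (length(hits) > 1)
      stop_conflict(sprintf(
        "wing '%s' matches multiple homes (%s); add an explicit alias",
        w, paste(hits, collapse = ", ")))
    if (length(hits) == 1) hits else NA_character_
  }
  data.frame(wing_name = wing_names,
             home_id = vapply(wing_names, assign_one, ""),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Deterministic resident pseudonym
#'
#' Keyed SHA-256 digest of the normalized resident name and birth date.
#' Normalization case-folds, strips punctuation and collapses whitespace, so
#' `"SMITH, John"` and `"john smith"` with the same birth date yield the same
#' identifier. No inverse operation is exposed.
#'
#' @param name resident name (non-empty).
#' @param birth_date birth date (ISO 8601 string or Date); may be `NA`, in
#'   which case identity falls back to name only.
#' @param key secret key string.
#' @return character vector of 64-hex-digit resident ids.
#' @export
pseudonymize <- function(name, birth_date, key) {
  if (any(is.na(name)) || any(!nzchar(trimws(name))))
    stop_contract("resident name must be non-empty")
  norm <- normalize_name(name)
  bd <- ifelse(is.na(birth_date), "", as.character(birth_date))
  vapply(paste(norm, bd, sep = "|"), function(msg)
    digest::hmac(key, msg, algo = "sha256"), "", USE.NAMES = FALSE)
}

normalize_name <- function(name) {
  x <- tolower(name)
  x <- gsub("[[:punct:]]", " ", x)
  x <- gsub("[[:space:]]+", " ", trimws(x))
  # order-insensitive token form so "smith john" == "john smith"
  vapply(strsplit(x, " ", fixed = TRUE),
         function(t) paste(sort(t), collapse = " "), "")
}

display_token <- function(resident_id) toupper(substr(resident_id, 1, 8))

#' Assemble a point-in-time upload snapshot
#'
#' Combines parsed export content, wing-to-home assignment and the
#' pseudonymization key into an upload snapshot: residents pseudonymized,
#' medications linked to resident and home, records ceased before the
#' snapshot timestamp excluded, and residents in unassigned wings excluded
#' (and counted).
#'
#' @param parsed output of [read_export()].
#' @param wing_assignment output of [link_wings()].
#' @param timestamp snapshot timestamp (ISO 8601 string or Date); an explicit
#'   input, never the wall clock.
#' @param key pseudonymization key.
#' @param pharmacy_id identifier of the supplying pharmacy.
#' @param snapshot_label e.g. `"baseline"`, `"month3"`, `"month6"`.
#' @return an object of class `sedetl_snapshot`.
#' @export
assemble_upload <- function(parsed, wing_assignment, timestamp, key,
                            pharmacy_id = "pharmacy", snapshot_label = "baseline") {
  ts <- as.Date(timestamp)
  res_raw <- parsed$residents
  rows <- parsed$rows
  wa <- stats::setNames(wing_assignment$home_id, wing_assignment$wing_name)

  res_raw$home_id <- unname(wa[res_raw$wing_name])
  excluded_residents <- sum(is.na(res_raw$home_id))
  res_raw <- res_raw[!is.na(res_raw$home_id), , drop = FALSE]

  res_raw$resident_id <- pseudonymize(res_raw$name, res_raw$birth_date, key)
  # a pharmacy may hold several profiles for one person (e.g. split packs);
  # profiles are kept distinct per source key and merged only by the explicit
  # phase-4 workflow, so the pseudonym is suffixed per source profile
  identity_key <- res_raw$resident_id
  suffix <- stats::ave(seq_along(identity_key), identity_key, FUN = seq_along)
  res_raw$identity_key <- identity_key
  res_raw$resident_id <- paste0(substr(identity_key, 1, 16), "-", suffix)

  residents <- data.frame(
    resident_id = res_raw$resident_id,
    identity_key = res_raw$identity_key,
    display_token = display_token(res_raw$identity_key),
    home_id = res_raw$home_id,
    wing = res_raw$wing_name,
    source = "uploaded",
    source_key = res_raw$resident_key,
    merged_into = NA_character_,
    stringsAsFactors = FALSE)

  key_to_id <- stats::setNames(res_raw$resident_id, res_raw$resident_key)
  rows$resident_id <- unname(key_to_id[rows$resident_key])
  in_excluded_wing <- rows$wing_name %in%
    wing_assignment$wing_name[is.na(wing_assignment$home_id)]
  excluded_med_rows <- sum(in_excluded_wing)
  rows <- rows[!in_excluded_wing, , drop = FALSE]
  if (any(is.na(rows$resident_id)))
    stop_integrity(sprintf(
      "medication rows reference unknown residents: %s",
      paste(unique(rows$resident_key[is.na(rows$resident_id)]), collapse = ", ")))

  ceased <- !is.na(rows$date_ceased) & as.Date(rows$date_ceased) < ts
  excluded_ceased <- sum(ceased)
  rows <- rows[!ceased, , drop = FALSE]

  rows$home_id <- unname(wa[rows$wing_name])
  meds <- rows[c("resident_id", "resident_key", "home_id", "vendor",
                 "vendor_med_id", "med_name", "instructions",
                 "quantity_supplied", "date_started", "date_ceased",
                 "prescriber")]
  meds$source <- "uploaded"
  rownames(meds) <- NULL

  structure(list(
    pharmacy_id = pharmacy_id,
    snapshot_label = snapshot_label,
    timestamp = as.character(ts),
    home_ids = sort(unique(residents$home_id)),
    residents = residents,
    medications = meds,
    counts = list(
      residents = nrow(residents),
      medications = nrow(meds),
      excluded_residents_unassigned_wing = excluded_residents,
      excluded_medications_unassigned_wing = excluded_med_rows,
      excluded_medications_ceased = excluded_ceased,
      rejected_rows = nrow(parsed$rejects))
  ), class = "sedetl_snapshot")
}

#' Combine several pharmacy snapshots into one study snapshot
#'
#' Uploads from different pharmacies supplying the same participating homes
#' are concatenated; resident ids are already globally stable pseudonyms.
#'
#' @param snapshots list of `sedetl_snapshot` objects (same label).
#' @return a combined `sedetl_snapshot`.
#' @export
combine_snapshots <- function(snapshots) {
  stopifnot(length(snapshots) >= 1)
  res <- do.call(rbind, lapply(snapshots, `[[`, "residents"))
  # the same source profile can appear in two uploads; keep first
  res <- res[!duplicated(res$resident_id), , drop = FALSE]
  meds <- do.call(rbind, lapply(snapshots, `[[`, "medications"))
  rownames(res) <- rownames(meds) <- NULL
  structure(list(
    pharmacy_id = paste(unique(vapply(snapshots, `[[`, "", "pharmacy_id")),
                        collapse = "+"),
    snapshot_label = snapshots[[1]]$snapshot_label,
    timestamp = snapshots[[1]]$timestamp,
    home_ids = sort(unique(res$home_id)),
    residents = res,
    medications = meds,
    counts = list(residents = nrow(res), medications = nrow(meds))
  ), class = "sedetl_snapshot")
}
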