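# Dosing-instruction parsing, daily dose, WHO DDD ratios and sedative-load
# aggregation in diazepam / chlorpromazine milligram equivalents.

# reference ATC rows used for equivalence scaling
ATC_DIAZEPAM <- "N05BA01"
ATC_CHLORPROMAZINE <- "N05AA01"

FREQ_TOKENS <- c(mane = 1, nocte = 1, midday = 1, daily = 1, od = 1,
                 bd = 2, tds = 3, qid = 4)
COUNT_WORDS <- c(quarter = 0.25, half = 0.5, one = 1, two = 2, three = 3,
                 four = 4, five = 5, six = 6)
FILLER_WORDS <- c("tablet", "tablets", "tab", "tabs", "capsule", "capsules",
                  "cap", "caps", "take", "a", "the", "at", "in", "with",
                  "of", "each", "every", "day", "night", "morning", "and")

#' Parse a dosing instruction into a dose schedule
#'
#' Recognizes a small additive grammar over pharmacy sig shorthand: each part
#' is a count token (integer, decimal, or word such as "half" = 0.5)
#' followed by a frequency token (mane, nocte, midday, daily = 1; bd = 2;
#' tds = 3; qid = 4), with multi-part instructions summed ("one mane and two
#' nocte" gives 3 units/day). PRN phrases mark the schedule PRN without
#' affecting the numeric fields. Text outside the grammar is returned as
#' `unparseable` rather than guessed, so it can be flagged for human review;
#' absent text is `missing`.
#'
#' @param instructions a single instruction string (or `NA`).
#' @return list with `units_per_administration`, `administrations_per_day`,
#'   `prn`, `parse_status` (`"parsed"`, `"unparseable"`, `"missing"`).
#' @export
parse_schedule <- function(instructions) {
  as.list(parse_schedules(instructions)[1, ])
}

#' Vectorized instruction parsing
#'
#' @param instructions character vector.
#' @return data frame with one row per instruction; see [parse_schedule()].
#' @export
parse_schedules <- function(instructions) {
  out <- data.frame(units_per_administration = rep(NA_real_, length(instructions)),
                    administrations_per_day = NA_real_,
                    prn = FALSE, parse_status = "unparseable",
                    stringsAsFactors = FALSE)
  prn_pattern <- paste0("\\b(", paste(PRN_TOKENS, collapse = "|"), ")\\b")
  for (i in seq_along(instructions)) {
    text <- instructions[[i]]
    if (is.na(text) || !nzchar(trimws(text))) {
      out$parse_status[i] <- "missing"
      next
    }
    x <- tolower(text)
    out$prn[i] <- grepl(prn_pattern, x, perl = TRUE)
    x <- gsub(prn_pattern, " ", x, perl = TRUE)
    # strip punctuation but keep decimal points inside numbers
    x <- gsub("[^[:alnum:]. ]", " ", x)
    x <- gsub("(?<![0-9])\\.|\\.(?![0-9])", " ", x, perl = TRUE)
    # "and" separates additive parts; split before dropping filler
    parts <- strsplit(x, "\\band\\b", perl = TRUE)[[1]]
    daily_units <- 0
    n_admin <- 0
    ok <- length(parts) > 0
    for (part in parts) {
      toks <- strsplit(trimws(gsub("[[:space:]]+", " ", part)), " ")[[1]]
      toks <- toks[nzchar(toks)]
      toks <- toks[!toks %in% FILLER_WORDS]
      if (!length(toks)) next
      freq_idx <- which(toks %in% names(FREQ_TOKENS))
      if (length(freq_idx) != 1) { ok <- FALSE; break }
      freq <- FREQ_TOKENS[[toks[freq_idx]]]
      rest <- toks[-freq_idx]
      count <- 1
      if (length(rest) == 1) {
        if (rest %in% names(COUNT_WORDS)) count <- COUNT_WORDS[[rest]]
        else if (grepl("^[0-9]*\\.?[0-9]+$", rest)) count <- as.numeric(rest)
        else { ok <- FALSE; break }
      } else if (length(rest) > 1) { ok <- FALSE; break }
      daily_units <- daily_units + count * freq
      n_admin <- n_admin + freq
    }
    if (ok && n_admin > 0) {
      out$administrations_per_day[i] <- n_admin
      out$units_per_administration[i] <- daily_units / n_admin
      out$parse_status[i] <- "parsed"
    }
  }
  out
}

#' Daily dose in milligrams
#'
#' `units_per_administration * administrations_per_day * strength`, where
#' strength is the MPUU's mass per unit of use.
#'
#' @param schedule a parsed schedule (list or one-row data frame from
#'   [parse_schedule()]).
#' @param mpuu_strength strength in mg per unit (> 0).
#' @return daily dose in mg/day, or `NA` when the schedule is unparseable or
#'   missing.
#' @export
daily_dose_mg <- function(schedule, mpuu_strength) {
  if (!is.na(mpuu_strength) && mpuu_strength <= 0)
    stop_contract("mpuu_strength must be positive")
  if (!identical(schedule$parse_status, "parsed")) return(NA_real_)
  schedule$units_per_administration * schedule$administrations_per_day *
    mpuu_strength
}

ddd_value_for <- function(atc_code, ddd_table) {
  idx <- match(atc_code, ddd_table$atc_code)
  if (anyNA(idx))
    stop_sedetl(sprintf("no DDD reference row for ATC code %s",
                        paste(atc_code[is.na(idx)], collapse = ", ")),
                "sedetl_config_error")
  as.numeric(ddd_table$ddd_value[idx])
}

#' Ratio of a daily dose to the WHO Defined Daily Dose
#'
#' @param daily_dose_mg daily dose in mg/day.
#' @param atc_code the drug's ATC code (must have a row in `ddd_table`).
#' @param ddd_table data frame `atc_code`, `ddd_value`, `ddd_unit`.
#' @return `daily_dose_mg / DDD`, in DDD units per day.
#' @export
ddd_ratio <- function(daily_dose_mg, atc_code, ddd_table) {
  daily_dose_mg / ddd_value_for(atc_code, ddd_table)
}

#' Convert a daily dose to reference-drug milligram equivalents
#'
#' Benzodiazepine doses are expressed as diazepam mg/day and antipsychotic
#' doses as chlorpromazine mg/day. The default conversion scales by DDD
#' ratio: `dose / DDD(drug) * DDD(reference)`, which is exact for the
#' reference drug itself and linear in dose. A per-drug clinical equivalence
#' table, when supplied, overrides the DDD-ratio default.
#'
#' @param daily_dose_mg daily dose in mg/day.
#' @param atc_code the drug's ATC code.
#' @param class_label `"BENZODIAZEPINE"` or `"ANTIPSYCHOTIC"`.
#' @param ddd_table DDD reference table.
#' @param equivalents optional data frame `atc_code`,
#'   `reference_mg_per_drug_mg`: direct multiplicative conversion factors.
#' @return equivalent dose in mg/day of the reference drug.
#' @export
equivalent_dose <- function(daily_dose_mg, atc_code, class_label, ddd_table,
                            equivalents = NULL) {
  if (!class_label %in% c("BENZODIAZEPINE", "ANTIPSYCHOTIC"))
    stop_contract("equivalent_dose is defined only for sedative classes")
  if (!is.null(equivalents)) {
    idx <- match(atc_code, equivalents$atc_code)
    if (!is.na(idx))
      return(daily_dose_mg * as.numeric(equivalents$reference_mg_per_drug_mg[idx]))
  }
  ref <- if (class_label == "BENZODIAZEPINE") ATC_DIAZEPAM else ATC_CHLORPROMAZINE
  ddd_ratio(daily_dose_mg, atc_code, ddd_table) * ddd_value_for(ref, ddd_table)
}

#' Per-resident sedative load
#'
#' Sums equivalent daily doses over a resident's regular (non-PRN) sedative
#' records. PRN sedatives are excluded from the sums (administered PRN
#' quantities cannot be derived from packing data) and counted in
#' `excluded_prn_count`; sedatives whose dose could not be parsed are
#' excluded and counted in `excluded_unparsed_count`.
#'
#' @param records enriched medication rows for a single resident.
#' @param ddd_table DDD reference table.
#' @param equivalents optional equivalence override table.
#' @return one-row data frame: `resident_id`,
#'   `benzodiazepine_diazepam_equiv_mg_per_day`,
#'   `antipsychotic_chlorpromazine_equiv_mg_per_day`, `ddd_sum`,
#'   `excluded_prn_count`, `excluded_unparsed_count`.
#' @export
resident_load <- function(records, ddd_table, equivalents = NULL) {
  rid <- unique(records$resident_id)
  if (length(rid) > 1)
    stop_contract("resident_load expects records of a single resident")
  sed <- records[records$class %in% c("BENZODIAZEPINE", "ANTIPSYCHOTIC"), ,
                 drop = FALSE]
  prn <- sed$prn
  reg <- sed[!prn, , drop = FALSE]
  unparsed <- is.na(reg$daily_dose_mg)
  usable <- reg[!unparsed, , drop = FALSE]
  benzo <- apo <- dddsum <- 0
  if (nrow(usable)) {
    eq <- mapply(equivalent_dose, usable$daily_dose_mg, usable$atc_code,
                 usable$class, MoreArgs = list(ddd_table = ddd_table,
                                               equivalents = equivalents))
    benzo <- sum(eq[usable$class == "BENZODIAZEPINE"])
    apo <- sum(eq[usable$class == "ANTIPSYCHOTIC"])
    dddsum <- sum(ddd_ratio(usable$daily_dose_mg, usable$atc_code, ddd_table))
  }
  data.frame(
    resident_id = if (length(rid)) rid else NA_character_,
    benzodiazepine_diazepam_equiv_mg_per_day = benzo,
    antipsychotic_chlorpromazine_equiv_mg_per_day = apo,
    ddd_sum = dddsum,
    excluded_prn_count = sum(prn),
    excluded_unparsed_count = sum(unparsed),
    stringsAsFactors = FALSE)
}
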