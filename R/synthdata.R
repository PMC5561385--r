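# Synthetic fixture generator: terminology bundle, homes, residents,
# medication exports in both dialects, injected error modes, and a
# ground-truth ledger, so every pipeline stage and every recovery property is
# testable offline.
#
# Default magnitudes mirror the study setting this pipeline audits: ~90
# residents per home (SD 37.5), ~11.8 medication records per uploaded
# resident, ~5.1% of records sedative, ~45% of sedatives PRN, ~11.1%
# duplicate resident profiles, and packing omission rates of ~3.6% (regular)
# and ~6.1% (PRN) among sedatives. All are configurable; synthetic runs make
# no claim to reproduce any real study's exact counts.

VENDORS <- c("alpha_pack", "beta_pack", "gamma_dose", "delta_med")
# alpha/beta identify products at TPUU level, gamma/delta at CTPP level
VENDOR_TARGET_KIND <- c(alpha_pack = "TPUU", beta_pack = "TPUU",
                        gamma_dose = "CTPP", delta_med = "CTPP")

#' Synthetic generator configuration
#'
#' @param seed integer RNG seed; identical seeds give identical outputs.
#' @param n_homes number of participating homes.
#' @param residents_per_home_mean,residents_per_home_sd normal draw for home
#'   size (defaults 90 and 37.5), floored at 5.
#' @param meds_per_resident_mean Poisson mean medication records per resident
#'   (default 11.84).
#' @param sedative_fraction probability a record is a sedative (default
#'   0.0513).
#' @param prn_fraction PRN probability among sedative records (default
#'   0.4506, the PRN share of sedative records in the audited setting).
#' @param nonsed_prn_fraction PRN probability among non-sedatives (0.15).
#' @param duplicate_resident_rate probability a resident has a second
#'   (split-pack) profile (default 0.1107).
#' @param unmapped_medication_rate probability a sedative record carries a
#'   vendor code absent from the terminology map (default 0.01).
#' @param missing_dose_rate probability a sedative record loses its packed
#'   quantity (default 0.08).
#' @param corruption_rate probability a sedative record has transposed
#'   fields (instructions and prescriber swapped; default 0.02).
#' @param prn_omission_rate,regular_omission_rate probability a PRN / regular
#'   sedative record is absent from the packing export entirely (defaults
#'   0.0612 and 0.0362).
#' @param dup_copy_rate probability a duplicate profile carries one exact
#'   copy of a medication row (default 0.3).
#' @param two_home_upload_rate probability a pharmacy supplies two homes
#'   (default 0.22).
#' @param dialect_mix named probabilities over export dialects.
#' @return a `sedetl_genconfig` list.
#' @export
generator_config <- function(seed = 1L, n_homes = 4L,
                             residents_per_home_mean = 90,
                             residents_per_home_sd = 37.5,
                             meds_per_resident_mean = 11.84,
                             sedative_fraction = 0.0513,
                             prn_fraction = 0.4506,
                             nonsed_prn_fraction = 0.15,
                             duplicate_resident_rate = 0.1107,
                             unmapped_medication_rate = 0.01,
                             missing_dose_rate = 0.08,
                             corruption_rate = 0.02,
                             prn_omission_rate = 0.0612,
                             regular_omission_rate = 0.0362,
                             dup_copy_rate = 0.3,
                             two_home_upload_rate = 0.22,
                             dialect_mix = c(table_export = 0.5, report = 0.5)) {
  cfg <- as.list(environment())
  rates <- cfg[grepl("rate$|fraction$", names(cfg))]
  stopifnot(all(unlist(rates) >= 0), all(unlist(rates) <= 1))
  structure(cfg, class = "sedetl_genconfig")
}

# the fixture drug catalogue; DDD values are synthetic-but-plausible
# placeholders for the WHO reference values, which drop in unchanged
drug_catalogue <- function() {
  d <- function(drug, atc, strength, ddd, cls, atc2 = NA_character_,
                ddd2 = NA_real_)
    data.frame(drug = drug, atc = atc, strength_mg = strength, ddd_mg = ddd,
               class_true = cls, atc2 = atc2, ddd2_mg = ddd2,
               stringsAsFactors = FALSE)
  rbind(
    d("diazepam",        "N05BA01", 5,    10,   "BENZODIAZEPINE"),
    d("oxazepam",        "N05BA04", 15,   50,   "BENZODIAZEPINE"),
    d("temazepam",       "N05CD07", 10,   20,   "BENZODIAZEPINE"),
    d("nitrazepam",      "N05CD02", 5,    5,    "BENZODIAZEPINE"),
    d("clonazepam",      "N03AE01", 0.5,  8,    "BENZODIAZEPINE"),
    d("zopiclone",       "N05CF01", 7.5,  7.5,  "BENZODIAZEPINE"),
    d("zolpidem",        "N05CF02", 10,   10,   "BENZODIAZEPINE"),
    # combination product whose sedative component is a secondary assignment
    d("amitriptyline-chlordiazepoxide", "N06CA01", 12.5, 75,
      "BENZODIAZEPINE", atc2 = "N05BA02", ddd2 = 30),
    d("chlorpromazine",  "N05AA01", 25,   300,  "ANTIPSYCHOTIC"),
    d("haloperidol",     "N05AD01", 0.5,  8,    "ANTIPSYCHOTIC"),
    d("quetiapine",      "N05AH04", 25,   400,  "ANTIPSYCHOTIC"),
    d("olanzapine",      "N05AH03", 5,    10,   "ANTIPSYCHOTIC"),
    d("risperidone",     "N05AX08", 0.5,  5,    "ANTIPSYCHOTIC"),
    d("perphenazine",    "N05AB03", 4,    30,   "ANTIPSYCHOTIC"),
    # Table-1-style exclusions: psycholeptic codes carved out of N05A
    d("lithium",         "N05AN01", 250,  750,  "NONE"),
    d("prochlorperazine","N05AB04", 5,    100,  "NONE"),
    # non-sedative distractors
    d("paracetamol",     "N02BE01", 500,  3000, "NONE"),
    d("metformin",       "A10BA02", 500,  2000, "NONE"),
    d("atorvastatin",    "C10AA05", 20,   20,   "NONE"),
    d("sertraline",      "N06AB06", 50,   50,   "NONE"),
    d("pantoprazole",    "A02BC02", 40,   40,   "NONE"),
    d("furosemide",      "C03CA01", 40,   40,   "NONE"),
    d("donepezil",       "N06DA02", 10,   7.5,  "NONE")
  )
}

#' Generate the synthetic terminology bundle
#'
#' Builds a complete AMT-style bundle over the fixture drug catalogue: one
#' MPUU per drug+strength, two branded TPUUs, a TPP and a CTPP chain above
#' the first brand, vendor-code maps for four packing systems (two
#' identifying products at TPUU level, two at CTPP level), ATC assignments
#' (with one combination product carrying its sedative code as a secondary
#' assignment), and a DDD reference table including the diazepam and
#' chlorpromazine reference rows. Fully deterministic.
#'
#' @param config a `sedetl_genconfig` (unused except for interface symmetry;
#'   the vocabulary is fixed).
#' @return a validated `sedetl_bundle`, with attribute `"catalogue"` carrying
#'   the generator's drug table extended with concept and vendor-code ids.
#' @export
generate_terminology <- function(config = generator_config()) {
  cat <- drug_catalogue()
  n <- nrow(cat)
  base <- 60000000000 + seq_len(n) * 1000
  cat$mpuu_id <- base + 1
  cat$tpuu1_id <- base + 2
  cat$tpuu2_id <- base + 3
  cat$tpp_id <- base + 4
  cat$ctpp_id <- base + 5
  brand1 <- paste0(toupper(substr(cat$drug, 1, 3)), "ON")
  brand2 <- paste0(toupper(substr(cat$drug, 1, 3)), "EZE")
  unit_name <- sprintf("%s %g mg tablet", cat$drug, cat$strength_mg)

  concepts <- rbind(
    data.frame(concept_id = cat$mpuu_id, kind = "MPUU",
               preferred_name = unit_name, strength_value = cat$strength_mg,
               strength_unit = "mg", dose_form = "tablet",
               stringsAsFactors = FALSE),
    data.frame(concept_id = cat$tpuu1_id, kind = "TPUU",
               preferred_name = sprintf("%s %g mg tablet", brand1,
                                        cat$strength_mg),
               strength_value = cat$strength_mg, strength_unit = "mg",
               dose_form = "tablet", stringsAsFactors = FALSE),
    data.frame(concept_id = cat$tpuu2_id, kind = "TPUU",
               preferred_name = sprintf("%s %g mg tablet", brand2,
                                        cat$strength_mg),
               strength_value = cat$strength_mg, strength_unit = "mg",
               dose_form = "tablet", stringsAsFactors = FALSE),
    data.frame(concept_id = cat$tpp_id, kind = "TPP",
               preferred_name = sprintf("%s %g mg tablet, 25", brand1,
                                        cat$strength_mg),
               strength_value = NA_real_, strength_unit = NA_character_,
               dose_form = NA_character_, stringsAsFactors = FALSE),
    data.frame(concept_id = cat$ctpp_id, kind = "CTPP",
               preferred_name = sprintf("%s %g mg tablet, 25, blister pack",
                                        brand1, cat$strength_mg),
               strength_value = NA_real_, strength_unit = NA_character_,
               dose_form = NA_character_, stringsAsFactors = FALSE))

  edges <- rbind(
    data.frame(child_id = cat$tpuu1_id, parent_id = cat$mpuu_id,
               relation = "is_generic_of", stringsAsFactors = FALSE),
    data.frame(child_id = cat$tpuu2_id, parent_id = cat$mpuu_id,
               relation = "is_generic_of", stringsAsFactors = FALSE),
    data.frame(child_id = cat$tpp_id, parent_id = cat$tpuu1_id,
               relation = "contains", stringsAsFactors = FALSE),
    data.frame(child_id = cat$ctpp_id, parent_id = cat$tpp_id,
               relation = "contains", stringsAsFactors = FALSE))

  code_for <- function(vendor, i) {
    prefix <- c(alpha_pack = "AP", beta_pack = "BP", gamma_dose = "GD",
                delta_med = "DM")[[vendor]]
    sprintf("%s%04d", prefix, 1000 + i)
  }
  vendor_map <- do.call(rbind, lapply(VENDORS, function(v) {
    target <- if (VENDOR_TARGET_KIND[[v]] == "TPUU") {
      if (v == "alpha_pack") cat$tpuu1_id else cat$tpuu2_id
    } else cat$ctpp_id
    data.frame(vendor = v, vendor_code = code_for(v, seq_len(n)),
               target_concept_id = target, origin = "automatic",
               equivalent_of_name = NA_character_, stringsAsFactors = FALSE)
  }))
  for (v in VENDORS) cat[[paste0("code_", v)]] <- code_for(v, seq_len(n))

  atc_map <- rbind(
    data.frame(mpuu_id = cat$mpuu_id, atc_code = cat$atc, primary = TRUE,
               stringsAsFactors = FALSE),
    data.frame(mpuu_id = cat$mpuu_id[!is.na(cat$atc2)],
               atc_code = cat$atc2[!is.na(cat$atc2)], primary = FALSE,
               stringsAsFactors = FALSE))

  ddd <- rbind(
    data.frame(atc_code = cat$atc, ddd_value = cat$ddd_mg, ddd_unit = "mg",
               stringsAsFactors = FALSE),
    data.frame(atc_code = cat$atc2[!is.na(cat$atc2)],
               ddd_value = cat$ddd2_mg[!is.na(cat$atc2)], ddd_unit = "mg",
               stringsAsFactors = FALSE))
  ddd <- ddd[!duplicated(ddd$atc_code), , drop = FALSE]

  bundle <- terminology_bundle(concepts, edges, vendor_map, atc_map, ddd)
  attr(bundle, "catalogue") <- cat
  bundle
}

FIRST_NAMES <- c("Alice", "Brian", "Clara", "David", "Edith", "Frank",
                 "Grace", "Henry", "Irene", "Jack", "Kathleen", "Leo",
                 "Mabel", "Norman", "Olive", "Peter", "Queenie", "Ronald",
                 "Sylvia", "Thomas", "Una", "Victor", "Wendy", "Xavier",
                 "Yvonne", "Zachary", "Agnes", "Bert", "Cora", "Douglas",
                 "Elsie", "Fred")
LAST_NAMES <- c("Anderson", "Brown", "Clarke", "Davies", "Evans", "Fisher",
                "Green", "Harris", "Irwin", "Johnson", "Kelly", "Lewis",
                "Mitchell", "Nguyen", "OBrien", "Patterson", "Quinn",
                "Roberts", "Smith", "Taylor", "Underwood", "Vickers",
                "Walker", "Young", "Adams", "Bennett", "Carter", "Dawson",
                "Elliott", "Foster", "Gibson", "Hughes")

# fixed instruction pool: text, total units/day (grammar-evaluable)
schedule_pool <- function() {
  data.frame(
    instr = c("One tablet mane", "One tablet nocte", "Two tablets nocte",
              "Half tablet mane", "One tablet bd", "One tablet tds",
              "Two tablets daily", "One tablet midday",
              "one mane and one nocte", "One tablet qid", "Half tablet bd"),
    daily_units = c(1, 1, 2, 0.5, 2, 3, 2, 1, 2, 4, 1),
    stringsAsFactors = FALSE)
}

#' Generate synthetic pharmacy export files and the ground-truth ledger
#'
#' Draws homes, residents and medication records under the configured rates,
#' injects the configured error modes (omitted PRN/regular sedative records,
#' missing packed quantities, duplicate resident profiles with split packs,
#' unmapped vendor codes, transposed-field corruptions), writes one export
#' file per pharmacy in its dialect, and records every generated record and
#' every injection in a ledger.
#'
#' @param config a `sedetl_genconfig`.
#' @param bundle bundle from [generate_terminology()] (must carry its
#'   catalogue attribute).
#' @param out_dir directory for the export files.
#' @return list: `files` (per-pharmacy paths), `pharmacies` (id, dialect,
#'   vendor, homes), `registry` (home-id to wing aliases), `residents`
#'   (person-level truth incl. duplicate profiles), `records` (per-record
#'   truth and injection labels), `config`.
#' @export
generate_pharmacy_data <- function(config, bundle, out_dir) {
  cat <- attr(bundle, "catalogue")
  if (is.null(cat)) stop_contract("bundle lacks a generator catalogue")
  set.seed(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  homes <- sprintf("H%02d", seq_len(config$n_homes))
  wings <- c("East Wing", "West Wing")
  registry <- stats::setNames(lapply(homes, function(h)
    c(paste(h, wings), paste0(h, "-", c("E", "W")))), homes)

  # pharmacies: some supply two homes
  pharmacies <- list()
  i <- 1
  while (i <= length(homes)) {
    take <- if (i < length(homes) &&
                stats::runif(1) < config$two_home_upload_rate) 2 else 1
    pharmacies[[length(pharmacies) + 1]] <- homes[i:(i + take - 1)]
    i <- i + take
  }
  ph <- data.frame(
    pharmacy_id = sprintf("P%02d", seq_along(pharmacies)),
    vendor = VENDORS[(seq_along(pharmacies) - 1) %% length(VENDORS) + 1],
    dialect = sample(names(config$dialect_mix), length(pharmacies),
                     replace = TRUE, prob = config$dialect_mix),
    stringsAsFactors = FALSE)
  ph$homes <- pharmacies

  # residents (person level), unique name+dob globally
  n_per_home <- pmax(5L, round(stats::rnorm(length(homes),
                                            config$residents_per_home_mean,
                                            config$residents_per_home_sd)))
  n_people <- sum(n_per_home)
  name <- paste(sample(FIRST_NAMES, n_people, TRUE),
                sample(LAST_NAMES, n_people, TRUE))
  dob <- as.character(as.Date("1920-01-01") + sample.int(11000, n_people, TRUE))
  repeat {
    clash <- duplicated(paste(name, dob))
    if (!any(clash)) break
    dob[clash] <- as.character(as.Date("1920-01-01") +
                                 sample.int(11000, sum(clash), TRUE))
  }
  people <- data.frame(
    person_uid = sprintf("u%05d", seq_len(n_people)),
    name = name, birth_date = dob,
    home_id = rep(homes, n_per_home),
    wing = unlist(lapply(n_per_home, function(m) sample(wings, m, TRUE))),
    stringsAsFactors = FALSE)
  people$wing_name <- paste(people$home_id, people$wing)
  home_to_pharmacy <- stats::setNames(
    rep(ph$pharmacy_id, vapply(ph$homes, length, 0L)), unlist(ph$homes))
  people$pharmacy_id <- home_to_pharmacy[people$home_id]
  people$vendor <- ph$vendor[match(people$pharmacy_id, ph$pharmacy_id)]

  # duplicate (split-pack) profiles: a surname-first name variant of the same
  # person (normalizes to the same identity key); drawn here, realised after
  # record assignment
  people$has_duplicate <- stats::runif(n_people) < config$duplicate_resident_rate
  people$resident_key <- sprintf("R%05d", seq_len(n_people))

  # medication records
  n_meds <- stats::rpois(n_people, config$meds_per_resident_mean)
  total <- sum(n_meds)
  person_idx <- rep(seq_len(n_people), n_meds)
  is_sed_drug <- cat$class_true != "NONE"
  sed_pick <- stats::runif(total) < config$sedative_fraction
  drug_idx <- integer(total)
  drug_idx[sed_pick] <- sample(which(is_sed_drug), sum(sed_pick), TRUE)
  drug_idx[!sed_pick] <- sample(which(!is_sed_drug), sum(!sed_pick), TRUE)
  pool <- schedule_pool()
  sched_idx <- sample.int(nrow(pool), total, TRUE)
  prn <- ifelse(sed_pick,
                stats::runif(total) < config$prn_fraction,
                stats::runif(total) < config$nonsed_prn_fraction)

  rec <- data.frame(
    record_uid = sprintf("g%06d", seq_len(total)),
    person_uid = people$person_uid[person_idx],
    pharmacy_id = people$pharmacy_id[person_idx],
    home_id = people$home_id[person_idx],
    vendor = people$vendor[person_idx],
    drug = cat$drug[drug_idx],
    mpuu_id = cat$mpuu_id[drug_idx],
    atc = ifelse(is.na(cat$atc2[drug_idx]) | cat$class_true[drug_idx] == "NONE",
                 cat$atc[drug_idx], cat$atc2[drug_idx]),
    class_true = cat$class_true[drug_idx],
    prn = prn,
    instructions = ifelse(prn, paste(pool$instr[sched_idx], "PRN"),
                          pool$instr[sched_idx]),
    daily_units = pool$daily_units[sched_idx],
    strength_mg = cat$strength_mg[drug_idx],
    stringsAsFactors = FALSE)
  rec$daily_dose_mg <- rec$daily_units * rec$strength_mg
  rec$quantity_true <- as.integer(ceiling(rec$daily_units) * 28)
  # distinct start dates per resident so (resident, code, date) is unique
  rec$date_started <- as.character(as.Date("2015-06-01") -
    stats::ave(seq_len(total), person_idx, FUN = seq_along) * 3 -
    sample.int(3, total, TRUE) - 1)
  rec$prescriber <- paste("Dr", sample(LAST_NAMES, total, TRUE))

  # vendor codes; unmapped injection replaces the code with an unknown one
  vcode_cols <- paste0("code_", rec$vendor)
  rec$vendor_code_true <- cat[cbind(drug_idx, match(vcode_cols, names(cat)))]
  is_sed <- rec$class_true != "NONE"
  rec$unmapped <- is_sed & stats::runif(total) < config$unmapped_medication_rate
  rec$vendor_code_file <- ifelse(rec$unmapped, paste0("X", rec$record_uid),
                                 rec$vendor_code_true)
  rec$med_name_file <- sprintf("%s %g mg tablet", rec$drug, rec$strength_mg)

  # omission: sedative records absent from the packing export
  rec$omitted <- is_sed & ifelse(rec$prn,
    stats::runif(total) < config$prn_omission_rate,
    stats::runif(total) < config$regular_omission_rate)
  # missing packed quantity
  rec$missing_dose <- is_sed & !rec$omitted &
    stats::runif(total) < config$missing_dose_rate
  # transposed-field corruption: instructions <-> prescriber
  rec$corrupted <- is_sed & !rec$omitted & !rec$missing_dose &
    stats::runif(total) < config$corruption_rate
  rec$instructions_file <- ifelse(rec$corrupted, rec$prescriber,
                                  rec$instructions)
  rec$prescriber_file <- ifelse(rec$corrupted, rec$instructions,
                                rec$prescriber)
  rec$quantity_file <- ifelse(rec$missing_dose, NA_integer_,
                              rec$quantity_true)

  # assign records of duplicated people across their two profiles, and copy
  # one record exactly into the other profile
  rec$resident_key <- people$resident_key[person_idx]
  rec$dup_copy <- FALSE
  copies <- list()
  idx_by_person <- split(seq_len(total), person_idx)
  for (p in which(people$has_duplicate)) {
    mine <- idx_by_person[[as.character(p)]]
    mine <- mine[!rec$omitted[mine]]
    if (length(mine) < 2) { people$has_duplicate[p] <- FALSE; next }
    to_second <- mine[stats::runif(length(mine)) < 0.5]
    if (!length(to_second) || length(to_second) == length(mine))
      to_second <- mine[1]
    rec$resident_key[to_second] <- sub("^R", "D", rec$resident_key[to_second])
    if (stats::runif(1) < config$dup_copy_rate) {
      src <- rec[sample(mine, 1), , drop = FALSE]
      src$resident_key <- if (grepl("^D", src$resident_key))
        sub("^D", "R", src$resident_key) else sub("^R", "D", src$resident_key)
      src$record_uid <- paste0(src$record_uid, "c")
      src$dup_copy <- TRUE
      copies[[length(copies) + 1]] <- src
    }
  }
  if (length(copies)) rec <- rbind(rec, do.call(rbind, copies))
  dup <- people[people$has_duplicate, , drop = FALSE]
  if (nrow(dup)) {
    dup$resident_key <- sub("^R", "D", dup$resident_key)
    dup$name <- vapply(strsplit(dup$name, " "), function(p)
      paste0(toupper(p[2]), ", ", p[1]), "")
  }

  profiles <- rbind(
    cbind(people[c("person_uid", "name", "birth_date", "home_id", "wing",
                   "wing_name", "pharmacy_id", "vendor", "resident_key")],
          is_duplicate_profile = FALSE),
    if (nrow(dup)) cbind(dup[c("person_uid", "name", "birth_date", "home_id",
                               "wing", "wing_name", "pharmacy_id", "vendor",
                               "resident_key")],
                         is_duplicate_profile = TRUE))
  rownames(profiles) <- NULL

  # write one export per pharmacy
  files <- character(nrow(ph))
  for (j in seq_len(nrow(ph))) {
    pid <- ph$pharmacy_id[j]
    pres <- profiles[profiles$pharmacy_id == pid, , drop = FALSE]
    pres_out <- data.frame(resident_key = pres$resident_key,
                           name = pres$name, birth_date = pres$birth_date,
                           wing_name = pres$wing_name,
                           stringsAsFactors = FALSE)
    prec <- rec[rec$pharmacy_id == pid & !rec$omitted, , drop = FALSE]
    rows <- data.frame(
      vendor_med_id = prec$vendor_code_file,
      med_name = prec$med_name_file,
      instructions = prec$instructions_file,
      quantity_supplied = prec$quantity_file,
      date_started = prec$date_started,
      date_ceased = NA_character_,
      prescriber = prec$prescriber_file,
      resident_key = prec$resident_key,
      wing_name = pres$wing_name[match(prec$resident_key, pres$resident_key)],
      stringsAsFactors = FALSE)
    files[j] <- file.path(out_dir, sprintf("%s.%s.txt", pid, ph$dialect[j]))
    write_export(list(rows = rows, residents = pres_out,
                      wings = unique(pres_out$wing_name)),
                 files[j], ph$dialect[j], ph$vendor[j])
  }

  list(files = files, pharmacies = ph, registry = registry,
       residents = profiles, records = rec, config = config)
}

#' Generate the correction and interaction event streams for a session
#'
#' Emits phase-labelled corrections that exactly repair the injected errors
#' of a generated dataset, against an ingested state:
#' unmapped codes are mapped in phase 1 (a configurable fraction as
#' chemically-equivalent fallbacks), transposed fields restored in phase 2,
#' missing quantities and omitted records entered in phase 3 along with the
#' champion nurse's per-resident checks, and duplicate profiles merged in
#' phase 4. Also emits a timestamped interaction-event stream for session
#' time estimation.
#'
#' @param truth output of [generate_pharmacy_data()].
#' @param state the `sedetl_state` built from the generated files (ingested
#'   and enriched, before corrections).
#' @param fallback_fraction fraction of manual mappings recorded as
#'   chemically-equivalent fallbacks (default 0.2).
#' @return list: `corrections` (ordered list of `sedetl_log_entry`),
#'   `checks` (per-resident check entries, applied after phase-3
#'   corrections), `interactions` (event data frame).
#' @export
generate_session_log <- function(truth, state, fallback_fraction = 0.2) {
  set.seed(truth$config$seed + 1)
  rec <- truth$records
  cat <- attr(state$bundle, "catalogue")
  meds <- state$medications
  med_key <- paste(meds$vendor, meds$resident_key, meds$vendor_med_id,
                   meds$date_started, meds$instructions, sep = "\r")
  find_med <- function(r, instructions = r$instructions_file) {
    k <- paste(r$vendor, r$resident_key, r$vendor_code_file, r$date_started,
               instructions, sep = "\r")
    idx <- match(k, med_key)
    if (anyNA(idx))
      stop_integrity(sprintf("ledger record %s not found in state",
                             r$record_uid[is.na(idx)][1]))
    meds$med_id[idx]
  }
  res_by_key <- stats::setNames(state$residents$resident_id,
                                state$residents$source_key)
  entries <- list()
  push <- function(e) entries[[length(entries) + 1]] <<- e

  # P1: manual mappings for unmapped codes (deduplicated per vendor+code)
  um <- rec[rec$unmapped & !rec$omitted, , drop = FALSE]
  um <- um[!duplicated(paste(um$vendor, um$vendor_code_file)), , drop = FALSE]
  if (nrow(um)) {
    fb <- stats::runif(nrow(um)) < fallback_fraction
    for (i in seq_len(nrow(um))) {
      r <- um[i, ]
      di <- match(r$drug, cat$drug)
      target <- if (VENDOR_TARGET_KIND[[r$vendor]] == "TPUU") {
        if (r$vendor == "alpha_pack") cat$tpuu1_id[di] else cat$tpuu2_id[di]
      } else cat$ctpp_id[di]
      chg <- fc(c("target_concept_id", "origin"), c(NA, NA),
                c(as.character(target),
                  if (fb[i]) "equivalent_fallback" else "manual"))
      if (fb[i])
        chg <- rbind(chg, fc("equivalent_of_name", NA, r$med_name_file))
      push(log_entry("P1_mapping", "research_pharmacist", "add", "mapping",
                     paste(r$vendor, r$vendor_code_file, sep = ":"), chg))
    }
  }

  # P2: restore transposed fields
  co <- rec[rec$corrupted & !rec$omitted, , drop = FALSE]
  for (i in seq_len(nrow(co))) {
    r <- co[i, ]
    mid <- find_med(r)
    sched <- parse_schedule(r$instructions)
    push(log_entry("P2_offsite", "project_staff", "modify", "medication", mid,
                   fc(c("instructions", "prescriber", "parse_status", "prn",
                        "units_per_administration", "administrations_per_day",
                        "daily_dose_mg"),
                      c(r$instructions_file, r$prescriber_file, "unparseable",
                        detect_prn(r$instructions_file), NA, NA, NA),
                      c(r$instructions, r$prescriber, "parsed",
                        r$prn,
                        sched$units_per_administration,
                        sched$administrations_per_day,
                        r$daily_dose_mg))))
  }

  # P3: enter missing quantities, add omitted records
  md <- rec[rec$missing_dose & !rec$omitted, , drop = FALSE]
  for (i in seq_len(nrow(md))) {
    r <- md[i, ]
    push(log_entry("P3_inhome", "champion_nurse", "modify", "medication",
                   find_med(r),
                   fc("quantity_supplied", NA, r$quantity_true)))
  }
  om <- rec[rec$omitted, , drop = FALSE]
  for (i in seq_len(nrow(om))) {
    r <- om[i, ]
    sched <- parse_schedule(r$instructions)
    push(log_entry("P3_inhome", "champion_nurse", "add", "medication",
                   paste0("a", r$record_uid),
                   fc(c("resident_id", "resident_key", "home_id", "vendor",
                        "vendor_med_id", "med_name", "display_name",
                        "instructions", "quantity_supplied", "date_started",
                        "prescriber", "mpuu_id", "atc_code", "class", "prn",
                        "units_per_administration", "administrations_per_day",
                        "parse_status", "daily_dose_mg", "source"),
                      NA,
                      c(res_by_key[[r$resident_key]], r$resident_key,
                        r$home_id, r$vendor, r$vendor_code_true,
                        r$med_name_file, r$med_name_file, r$instructions,
                        r$quantity_true, r$date_started, r$prescriber,
                        r$mpuu_id, r$atc, r$class_true, r$prn,
                        sched$units_per_administration,
                        sched$administrations_per_day, "parsed",
                        r$daily_dose_mg, "manual"))))
  }

  # P3 checks: every active resident marked checked
  checks <- lapply(state$residents$resident_id, function(rid)
    log_entry("P3_inhome", "champion_nurse", "modify", "resident", rid,
              fc("checked", "FALSE", "TRUE")))

  # P4: merge duplicate profiles into the primary profile
  merges <- list()
  dups <- truth$residents[truth$residents$is_duplicate_profile, , drop = FALSE]
  for (i in seq_len(nrow(dups))) {
    src_key <- dups$resident_key[i]
    tgt_key <- sub("^D", "R", src_key)
    if (!src_key %in% names(res_by_key)) next
    merges[[length(merges) + 1]] <-
      log_entry("P4_retrospective", "project_staff", "merge", "resident",
                res_by_key[[src_key]],
                fc("merged_into", NA, res_by_key[[tgt_key]]))
  }

  # interaction events: one block of activity per (home, nurse), sized by
  # home occupancy, plus a smaller off-site block per pharmacy
  interactions <- do.call(rbind, lapply(unique(truth$residents$home_id),
    function(h) {
      n_ev <- max(3, sum(truth$residents$home_id == h &
                           !truth$residents$is_duplicate_profile) %/% 4)
      t0 <- as.POSIXct("2015-07-01 09:00:00", tz = "UTC") +
        stats::runif(1, 0, 3600)
      data.frame(actor = paste0("nurse_", h), home_id = h,
                 timestamp = format(t0 + cumsum(stats::runif(n_ev, 30, 300)),
                                    "%Y-%m-%dT%H:%M:%S"),
                 stringsAsFactors = FALSE)
    }))

  list(corrections = c(entries, checks, merges), checks = checks,
       interactions = interactions)
}
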