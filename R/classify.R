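# Sedative classification from ATC codes, and PRN (pro re nata) detection.
#
# The study definition of "sedative" is antipsychotics (ATC N05A, excluding
# lithium N05AN and prochlorperazine N05AB04) plus benzodiazepines and
# related drugs (N05BA anxiolytics, N05CD hypnotics, N05CF
# benzodiazepine-related "z-drugs", and clonazepam N03AE01). ATC membership
# is string-prefix membership: the code encodes its own hierarchy. Exclusions
# are refinements of an inclusion, and the longest matching prefix wins.

#' Default sedative classification rule set
#'
#' Inclusion prefixes with class labels, and exclusion prefixes, matching the
#' study definition of antipsychotics and benzodiazepines.
#'
#' @return a `sedetl_rules` object: list with `include` (data frame `prefix`,
#'   `class`) and `exclude` (character vector of refined prefixes).
#' @export
default_sedative_rules <- function() {
  rules <- list(
    include = data.frame(
      prefix = c("N05A", "N05BA", "N05CD", "N05CF", "N03AE01"),
      class  = c("ANTIPSYCHOTIC", "BENZODIAZEPINE", "BENZODIAZEPINE",
                 "BENZODIAZEPINE", "BENZODIAZEPINE"),
      stringsAsFactors = FALSE),
    exclude = c("N05AN", "N05AB04")
  )
  validate_rules(structure(rules, class = "sedetl_rules"))
}

#' Read a classification rule set from a YAML file
#'
#' The rule set is configuration, not code, so other drug classes can be
#' audited with the same pipeline. The file holds `include` (list of
#' `prefix`/`class` pairs) and `exclude` (list of prefixes).
#'
#' @param path YAML file path.
#' @return a `sedetl_rules` object.
#' @export
read_rules <- function(path) {
  y <- yaml::read_yaml(path)
  inc <- do.call(rbind, lapply(y$include, function(r)
    data.frame(prefix = r$prefix, class = r$class, stringsAsFactors = FALSE)))
  validate_rules(structure(
    list(include = inc, exclude = as.character(unlist(y$exclude %||% list()))),
    class = "sedetl_rules"))
}

validate_rules <- function(rules) {
  stopifnot(all(grepl(ATC_PATTERN, rules$include$prefix)),
            all(grepl(ATC_PATTERN, rules$exclude)))
  refines <- vapply(rules$exclude, function(e)
    any(startsWith(e, rules$include$prefix)), logical(1))
  if (!all(refines))
    stop_contract(sprintf(
      "exclusion '%s' does not refine any inclusion prefix",
      rules$exclude[!refines][1]))
  rules
}

#' Classify an ATC code under a sedative rule set
#'
#' A code belongs to an inclusion prefix iff the prefix starts the code
#' string. Exclusions are refined prefixes carved out of an inclusion; when
#' both an inclusion and an exclusion match, the longest matching prefix
#' decides, so an exclusion always beats the inclusion it refines, and
#' siblings of an excluded code (e.g. N05AB03 next to excluded N05AB04) stay
#' included.
#'
#' @param atc_code character vector of ATC codes.
#' @param rules a `sedetl_rules` object; default [default_sedative_rules()].
#' @return character vector: `"ANTIPSYCHOTIC"`, `"BENZODIAZEPINE"` or
#'   `"NONE"`.
#' @export
classify_atc <- function(atc_code, rules = default_sedative_rules()) {
  bad <- !grepl(ATC_PATTERN, atc_code)
  if (any(bad))
    stop_contract(sprintf("malformed ATC code '%s'", atc_code[bad][1]))
  vapply(atc_code, function(code) {
    inc <- rules$include$prefix[startsWith(code, rules$include$prefix)]
    exc <- rules$exclude[startsWith(code, rules$exclude)]
    if (!length(inc)) return("NONE")
    best_inc <- inc[which.max(nchar(inc))]
    if (length(exc) && max(nchar(exc)) > nchar(best_inc)) return("NONE")
    rules$include$class[rules$include$prefix == best_inc][1]
  }, "", USE.NAMES = FALSE)
}

PRN_TOKENS <- c("prn", "as required", "when required", "as needed")

#' Detect pro re nata (as-required) dosing
#'
#' A record is PRN when the packing system's own PRN flag is set, or — when
#' no vendor flag is present — when the instruction text contains a PRN
#' phrase ("prn", "as required", "when required", "as needed"),
#' case-insensitively. A present vendor flag dominates the text either way.
#'
#' @param instructions instruction text (vectorized).
#' @param vendor_prn_flag optional logical vendor flag; `NA`/`NULL` means
#'   absent.
#' @return logical vector.
#' @export
detect_prn <- function(instructions, vendor_prn_flag = NULL) {
  pattern <- paste0("\\b(", paste(PRN_TOKENS, collapse = "|"), ")\\b")
  from_text <- !is.na(instructions) &
    grepl(pattern, tolower(instructions), perl = TRUE)
  if (is.null(vendor_prn_flag)) return(from_text)
  flag <- rep_len(as.logical(vendor_prn_flag), length(from_text))
  ifelse(is.na(flag), from_text, flag)
}

#' Enrich medication records with terminology, class, PRN and daily dose
#'
#' Runs the full enrichment chain over a snapshot's medication rows:
#' vendor-code resolution to MPUU, ATC lookup, sedative classification (over
#' ALL ATC assignments of the MPUU, so a sedative use is never missed by a
#' secondary assignment), PRN detection, instruction parsing and daily-dose
#' computation. Unresolvable records are classed `PENDING` and surface via
#' [list_unmapped()]. The displayed name is always the vendor-supplied
#' medication name, so chemically-equivalent fallback mappings never change
#' what nursing staff see.
#'
#' @param snapshot an `sedetl_snapshot`.
#' @param bundle a `sedetl_bundle`.
#' @param rules a `sedetl_rules` object.
#' @return the snapshot with enriched `medications`: added columns `med_id`,
#'   `display_name`, `mpuu_id`, `atc_code`, `class`, `prn`,
#'   `units_per_administration`, `administrations_per_day`, `parse_status`,
#'   `daily_dose_mg`.
#' @export
enrich_snapshot <- function(snapshot, bundle, rules = default_sedative_rules()) {
  meds <- snapshot$medications
  n <- nrow(meds)
  meds$med_id <- sprintf("m%06d", seq_len(n))
  meds$display_name <- meds$med_name

  keyed <- paste(meds$vendor, meds$vendor_med_id, sep = "\r")
  uniq <- !duplicated(keyed)
  lut <- new.env(parent = emptyenv())
  for (i in which(uniq)) {
    assign(keyed[i],
           resolve_to_mpuu(meds$vendor[i], meds$vendor_med_id[i], bundle),
           envir = lut)
  }
  meds$mpuu_id <- vapply(keyed, function(k) get(k, envir = lut), 0.0,
                         USE.NAMES = FALSE)

  atc_primary <- rep(NA_character_, n)
  cls <- rep("PENDING", n)
  mapped <- !is.na(meds$mpuu_id)
  for (id in unique(meds$mpuu_id[mapped])) {
    codes <- atc_codes_for_mpuu(id, bundle)
    sel <- mapped & meds$mpuu_id == id
    if (!length(codes)) {
      atc_primary[sel] <- NA_character_
      cls[sel] <- "PENDING"          # mapped MPUU without ATC is still pending
      next
    }
    all_cls <- classify_atc(codes, rules)
    sed_i <- which(all_cls != "NONE")
    if (length(sed_i)) {
      # a sedative assignment wins even when secondary, and the record's
      # working ATC code follows it so DDD and equivalence lookups stay
      # within the sedative class
      atc_primary[sel] <- codes[[sed_i[1]]]
      cls[sel] <- all_cls[[sed_i[1]]]
    } else {
      atc_primary[sel] <- codes[[1]]
      cls[sel] <- "NONE"
    }
  }
  meds$atc_code <- atc_primary
  meds$class <- cls
  meds$prn <- detect_prn(meds$instructions)

  sched <- parse_schedules(meds$instructions)
  meds$units_per_administration <- sched$units_per_administration
  meds$administrations_per_day <- sched$administrations_per_day
  meds$parse_status <- sched$parse_status

  strength <- mpuu_strengths(meds$mpuu_id, bundle)
  meds$daily_dose_mg <- ifelse(
    sched$parse_status == "parsed" & !is.na(strength),
    sched$units_per_administration * sched$administrations_per_day * strength,
    NA_real_)
  snapshot$medications <- meds
  snapshot
}

mpuu_strengths <- function(mpuu_ids, bundle) {
  con <- bundle$concepts
  idx <- match(mpuu_ids, con$concept_id)
  s <- as.numeric(con$strength_value[idx])
  unit <- con$strength_unit[idx]
  ifelse(!is.na(unit) & unit != "mg", NA_real_, s)
}
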