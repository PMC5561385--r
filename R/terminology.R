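# AMT-style medicines terminology: concept hierarchy, vendor-code resolution
# and ATC assignment.
#
# The bundle holds seven concept kinds (MP, MPUU, MPP, TP, TPUU, TPP, CTPP),
# but only three edge pairs participate in vendor-code resolution:
#   CTPP -contains-> TPP -contains-> TPUU -is_generic_of-> MPUU
# Packing systems identify medications at either TPUU or CTPP level; both
# resolve to a unique MPUU, which carries the ATC assignment(s).

CONCEPT_KINDS <- c("MP", "MPUU", "MPP", "TP", "TPUU", "TPP", "CTPP")

# legal (child kind, parent kind, relation) triples for resolution traversal
LEGAL_EDGES <- data.frame(
  child_kind  = c("CTPP", "TPP", "TPUU"),
  parent_kind = c("TPP", "TPUU", "MPUU"),
  relation    = c("contains", "contains", "is_generic_of"),
  stringsAsFactors = FALSE
)

ATC_PATTERN <- "^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$"

#' Construct a terminology bundle
#'
#' Assembles and validates the five tables of a terminology bundle: the
#' concept table, the concept-edge table, the vendor-code map, the MPUU-to-ATC
#' map and the DDD reference table.
#'
#' @param concepts data frame with columns `concept_id`, `kind`,
#'   `preferred_name`, `strength_value`, `strength_unit`, `dose_form`.
#' @param edges data frame with columns `child_id`, `parent_id`, `relation`.
#' @param vendor_map data frame with columns `vendor`, `vendor_code`,
#'   `target_concept_id`, `origin`, `equivalent_of_name`.
#' @param atc_map data frame with columns `mpuu_id`, `atc_code`, `primary`.
#' @param ddd data frame with columns `atc_code`, `ddd_value`, `ddd_unit`.
#' @return an object of class `sedetl_bundle`.
#' @export
terminology_bundle <- function(concepts, edges, vendor_map, atc_map, ddd) {
  bundle <- structure(
    list(concepts = concepts, edges = edges, vendor_map = vendor_map,
         atc_map = atc_map, ddd = ddd),
    class = "sedetl_bundle"
  )
  validate_bundle(bundle)
  bundle
}

#' Validate terminology bundle invariants
#'
#' Checks concept-id uniqueness, edge legality between concept kinds,
#' acyclicity of the resolution subgraph, the single-MPUU-parent rule for
#' TPUUs, the single-TPUU-reachability rule for CTPPs, vendor-map key
#' uniqueness and target kinds, and ATC code syntax with exactly one primary
#' assignment per mapped MPUU.
#'
#' @param bundle a `sedetl_bundle`.
#' @return the bundle, invisibly; signals a terminology-integrity error
#'   naming the offending concept otherwise.
#' @export
validate_bundle <- function(bundle) {
  con <- bundle$concepts
  if (anyDuplicated(con$concept_id))
    stop_integrity(sprintf("duplicate concept_id: %s",
                           con$concept_id[duplicated(con$concept_id)][1]))
  if (!all(con$kind %in% CONCEPT_KINDS))
    stop_integrity("unknown concept kind in concept table")

  kind_of <- stats::setNames(con$kind, as.character(con$concept_id))
  ed <- bundle$edges
  if (nrow(ed)) {
    ck <- kind_of[as.character(ed$child_id)]
    pk <- kind_of[as.character(ed$parent_id)]
    if (anyNA(ck) || anyNA(pk))
      stop_integrity("edge references unknown concept id")
    key <- paste(ck, pk, ed$relation)
    legal <- paste(LEGAL_EDGES$child_kind, LEGAL_EDGES$parent_kind,
                   LEGAL_EDGES$relation)
    # edges outside the resolution chain are tolerated only if they pair
    # other kinds; the three traversal pairs must use the stated relation
    res_kinds <- ck %in% c("CTPP", "TPP", "TPUU") & pk %in% c("TPP", "TPUU", "MPUU")
    if (any(res_kinds & !(key %in% legal)))
      stop_integrity(sprintf("illegal edge %s -> %s (%s)",
                             ed$child_id[res_kinds & !(key %in% legal)][1],
                             ed$parent_id[res_kinds & !(key %in% legal)][1],
                             ed$relation[res_kinds & !(key %in% legal)][1]))
    res <- ed[key %in% legal, , drop = FALSE]
    if (has_cycle(res)) stop_integrity("resolution edge set contains a cycle")

    # every TPUU has exactly one MPUU parent
    tpuu_ids <- con$concept_id[con$kind == "TPUU"]
    gen <- res[res$relation == "is_generic_of", , drop = FALSE]
    n_par <- table(factor(as.character(gen$child_id),
                          levels = as.character(tpuu_ids)))
    bad <- names(n_par)[n_par != 1]
    if (length(bad))
      stop_integrity(sprintf("TPUU %s has %d MPUU parents (expected 1)",
                             bad[1], n_par[bad[1]]))

    # every CTPP reaches exactly one TPUU
    for (cid in con$concept_id[con$kind == "CTPP"]) {
      tp <- reachable_of_kind(cid, "TPUU", res, kind_of)
      if (length(tp) != 1)
        stop_integrity(sprintf("CTPP %s reaches %d TPUUs (expected 1)",
                               cid, length(tp)))
    }
  }

  vm <- bundle$vendor_map
  if (nrow(vm)) {
    if (anyDuplicated(vm[c("vendor", "vendor_code")]))
      stop_integrity("duplicate (vendor, vendor_code) in vendor map")
    tk <- kind_of[as.character(vm$target_concept_id)]
    if (anyNA(tk) || !all(tk %in% c("TPUU", "CTPP")))
      stop_integrity("vendor map target must be an existing TPUU or CTPP")
  }

  am <- bundle$atc_map
  if (nrow(am)) {
    if (!all(grepl(ATC_PATTERN, am$atc_code)))
      stop_integrity(sprintf("malformed ATC code '%s' in atc map",
                             am$atc_code[!grepl(ATC_PATTERN, am$atc_code)][1]))
    if (!all(kind_of[as.character(am$mpuu_id)] == "MPUU", na.rm = FALSE))
      stop_integrity("atc map row references a non-MPUU concept")
    nprim <- tapply(am$primary, am$mpuu_id, sum)
    if (any(nprim != 1))
      stop_integrity(sprintf(
        "MPUU %s has %d primary ATC assignments (expected exactly 1)",
        names(nprim)[nprim != 1][1], nprim[nprim != 1][1]))
  }
  invisible(bundle)
}

# DFS colouring cycle check on the (child -> parent) edge list
has_cycle <- function(edges) {
  if (!nrow(edges)) return(FALSE)
  adj <- split(as.character(edges$parent_id), as.character(edges$child_id))
  colour <- new.env(parent = emptyenv())
  visit <- function(v) {
    state <- mget(v, envir = colour, ifnotfound = 0L)[[1]]
    if (state == 1L) return(TRUE)
    if (state == 2L) return(FALSE)
    assign(v, 1L, envir = colour)
    for (w in adj[[v]] %||% character()) if (visit(w)) return(TRUE)
    assign(v, 2L, envir = colour)
    FALSE
  }
  any(vapply(names(adj), visit, logical(1)))
}

# all concepts of kind `kind` reachable from `id` along resolution edges
reachable_of_kind <- function(id, kind, edges, kind_of) {
  out <- character(); frontier <- as.character(id); seen <- character()
  while (length(frontier)) {
    nxt <- as.character(edges$parent_id[as.character(edges$child_id) %in% frontier])
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    out <- c(out, nxt[kind_of[nxt] == kind])
    frontier <- nxt
  }
  unique(out)
}

#' Read a terminology bundle from a directory of TSV files
#'
#' Expects `concepts.tsv`, `edges.tsv`, `vendor_map.tsv`, `atc_map.tsv` and
#' `ddd.tsv` (tab-separated, UTF-8, header row).
#'
#' @param dir directory path.
#' @return a validated `sedetl_bundle`.
#' @export
read_bundle <- function(dir) {
  f <- function(name) file.path(dir, name)
  am <- read_tsv_file(f("atc_map.tsv"))
  am$primary <- as.logical(am$primary)
  terminology_bundle(
    concepts   = read_tsv_file(f("concepts.tsv")),
    edges      = read_tsv_file(f("edges.tsv")),
    vendor_map = read_tsv_file(f("vendor_map.tsv")),
    atc_map    = am,
    ddd        = read_tsv_file(f("ddd.tsv"))
  )
}

#' Write a terminology bundle to a directory of TSV files
#'
#' @param bundle a `sedetl_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_file(bundle$concepts, file.path(dir, "concepts.tsv"))
  write_tsv_file(bundle$edges, file.path(dir, "edges.tsv"))
  write_tsv_file(bundle$vendor_map, file.path(dir, "vendor_map.tsv"))
  write_tsv_file(bundle$atc_map, file.path(dir, "atc_map.tsv"))
  write_tsv_file(bundle$ddd, file.path(dir, "ddd.tsv"))
  invisible(dir)
}

#' Resolve a vendor medication code to its MPUU
#'
#' Follows the mapped target concept (TPUU or CTPP) along the containment /
#' genericization chain CTPP-TPP-TPUU-MPUU to the unique generic unit-of-use
#' concept. Unmapped codes return `NA`; they surface through
#' [list_unmapped()].
#'
#' @param vendor vendor (packing-system) name.
#' @param vendor_code the packing system's medication identifier.
#' @param bundle a `sedetl_bundle`.
#' @return the MPUU concept id, or `NA` when the code is not mapped.
#' @export
resolve_to_mpuu <- function(vendor, vendor_code, bundle) {
  vm <- bundle$vendor_map
  hit <- vm$vendor == vendor & vm$vendor_code == vendor_code
  if (!any(hit)) return(NA_real_)
  target <- vm$target_concept_id[hit][1]
  kind_of <- stats::setNames(bundle$concepts$kind,
                             as.character(bundle$concepts$concept_id))
  ed <- bundle$edges
  node <- target
  repeat {
    k <- kind_of[[as.character(node)]]
    if (k == "MPUU") return(as.numeric(node))
    rel <- if (k == "TPUU") "is_generic_of" else "contains"
    parents <- ed$parent_id[ed$child_id == node & ed$relation == rel]
    expected <- c(CTPP = "TPP", TPP = "TPUU", TPUU = "MPUU")[[k]]
    parents <- parents[kind_of[as.character(parents)] == expected]
    if (length(parents) != 1)
      stop_integrity(sprintf(
        "concept %s (%s) has %d %s parents; terminology bundle is malformed",
        node, k, length(parents), expected))
    node <- parents[[1]]
  }
}

#' All ATC assignments of an MPUU
#'
#' @param mpuu_id MPUU concept id.
#' @param bundle a `sedetl_bundle`.
#' @return character vector of ATC codes, primary first; empty when no
#'   assignment exists.
#' @export
atc_codes_for_mpuu <- function(mpuu_id, bundle) {
  check_is_mpuu(mpuu_id, bundle)
  am <- bundle$atc_map[bundle$atc_map$mpuu_id == mpuu_id, , drop = FALSE]
  if (!nrow(am)) return(character())
  am$atc_code[order(!am$primary)]
}

#' Primary ATC code of an MPUU
#'
#' @inheritParams atc_codes_for_mpuu
#' @return the primary ATC code string, or `NA` when the MPUU has no
#'   assignment.
#' @export
mpuu_to_atc <- function(mpuu_id, bundle) {
  codes <- atc_codes_for_mpuu(mpuu_id, bundle)
  if (!length(codes)) NA_character_ else codes[[1]]
}

check_is_mpuu <- function(id, bundle) {
  k <- bundle$concepts$kind[bundle$concepts$concept_id == id]
  if (!length(k))
    stop_integrity(sprintf("concept %s does not exist", id))
  if (k != "MPUU")
    stop_contract(sprintf("concept %s has kind %s, expected MPUU", id, k))
  invisible(TRUE)
}

#' Add a manual or chemically-equivalent vendor-code mapping
#'
#' Records a mapping created by a research pharmacist for a code the
#' automatic linkage missed. When `equivalent_of_name` is given, the mapping
#' is a chemically-equivalent fallback: the target concept stands in for a
#' medication absent from the terminology, and downstream enrichment keeps
#' displaying the vendor-supplied medication name so nursing staff see the
#' name that appears on the prescription.
#'
#' @param bundle a `sedetl_bundle`.
#' @param vendor vendor name.
#' @param vendor_code the unmapped code.
#' @param target_concept_id id of an existing TPUU or CTPP concept.
#' @param equivalent_of_name the original medication name when the mapping is
#'   a chemical-equivalence fallback; `NULL` for a direct manual mapping.
#' @return the updated bundle, with an attribute `"log_entry"` describing the
#'   addition for the transaction log.
#' @export
add_manual_mapping <- function(bundle, vendor, vendor_code, target_concept_id,
                               equivalent_of_name = NULL) {
  vm <- bundle$vendor_map
  if (any(vm$vendor == vendor & vm$vendor_code == vendor_code))
    stop_conflict(sprintf("mapping for (%s, %s) already exists",
                          vendor, vendor_code))
  k <- bundle$concepts$kind[bundle$concepts$concept_id == target_concept_id]
  if (!length(k) || !(k %in% c("TPUU", "CTPP")))
    stop_contract("manual mapping target must be an existing TPUU or CTPP")
  origin <- if (is.null(equivalent_of_name)) "manual" else "equivalent_fallback"
  bundle$vendor_map <- rbind(vm, data.frame(
    vendor = vendor, vendor_code = vendor_code,
    target_concept_id = target_concept_id, origin = origin,
    equivalent_of_name = equivalent_of_name %||% NA_character_,
    stringsAsFactors = FALSE))
  attr(bundle, "log_entry") <- list(
    action = "add", entity_kind = "mapping",
    entity_id = paste(vendor, vendor_code, sep = ":"),
    field_changes = data.frame(
      field = c("target_concept_id", "origin"),
      old = NA_character_,
      new = c(as.character(target_concept_id), origin),
      stringsAsFactors = FALSE))
  bundle
}

#' List medication codes that failed automatic terminology linkage
#'
#' Aggregates the distinct unmapped (vendor, vendor_code) pairs in a snapshot
#' or enriched record set, with the medication name and occurrence count,
#' ordered by descending count — the worklist sent to a research pharmacist.
#'
#' @param x an `sedetl_snapshot`, `sedetl_state`, or a medication record data
#'   frame carrying `mpuu_id`.
#' @return data frame with columns `vendor`, `vendor_code`, `med_name`, `n`.
#' @export
list_unmapped <- function(x) {
  meds <- if (is.data.frame(x)) x
          else if (inherits(x, "sedetl_state")) active_medications(x)
          else x$medications
  if (!"mpuu_id" %in% names(meds))
    stop_contract("records have not been resolved; run enrichment first")
  um <- meds[is.na(meds$mpuu_id), , drop = FALSE]
  if (!nrow(um)) {
    return(data.frame(vendor = character(), vendor_code = character(),
                      med_name = character(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(
    list(n = seq_len(nrow(um))),
    by = list(vendor = um$vendor, vendor_code = um$vendor_med_id,
              med_name = um$med_name),
    FUN = length)
  agg[order(-agg$n, agg$vendor, agg$vendor_code), , drop = FALSE]
}
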