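# Shared fixtures and independent oracles for the test suite.

.fixtures <- new.env(parent = emptyenv())

# the synthetic terminology bundle (deterministic; cached per test run)
fixture_bundle <- function() {
  if (is.null(.fixtures$bundle))
    .fixtures$bundle <- generate_terminology(generator_config())
  .fixtures$bundle
}

fixture_catalogue <- function() attr(fixture_bundle(), "catalogue")

# alpha_pack vendor code for a named catalogue drug
code_of <- function(drug) {
  cat <- fixture_catalogue()
  cat$code_alpha_pack[match(drug, cat$drug)]
}

# ---------------------------------------------------------------------------
# hand-written mini export (table_export dialect, vendor alpha_pack):
# three residents in H01 (two of whom are the same person under variant
# names), one resident in an unknown wing, sedative + non-sedative +
# PRN + ceased + unmapped medication rows.
write_mini_export <- function(path) {
  med <- function(code, name, instr, qty, start, ceased, presc, rkey, wing) {
    paste(code, name, instr, qty, start, ceased, presc, rkey, wing,
          sep = "\t")
  }
  lines <- c(
    "#sedetl-export\tdialect=table_export\tvendor=alpha_pack\tversion=1",
    "[residents]",
    "resident_key\tname\tbirth_date\twing_name",
    "R001\tMary Walker\t1930-04-02\tH01 East Wing",
    "R002\tJohn Smith\t1928-11-20\tH01 West Wing",
    "R003\tSMITH, John\t1928-11-20\tH01 East Wing",
    "R004\tEdna Quinn\t1933-01-15\tUnknown Annex",
    "[medications]",
    paste("vendor_med_id", "med_name", "instructions", "quantity_supplied",
          "date_started", "date_ceased", "prescriber", "resident_key",
          "wing_name", sep = "\t"),
    med(code_of("diazepam"), "diazepam 5 mg tablet", "One tablet nocte",
        "28", "2015-05-01", "", "Dr Green", "R001", "H01 East Wing"),
    med(code_of("temazepam"), "temazepam 10 mg tablet",
        "One tablet nocte PRN", "28", "2015-05-03", "", "Dr Green", "R001",
        "H01 East Wing"),
    med(code_of("paracetamol"), "paracetamol 500 mg tablet", "One tablet bd",
        "56", "2015-05-01", "", "Dr Green", "R001", "H01 East Wing"),
    med(code_of("lithium"), "lithium 250 mg tablet", "One tablet bd",
        "56", "2015-05-01", "", "Dr Brown", "R002", "H01 West Wing"),
    med(code_of("olanzapine"), "olanzapine 5 mg tablet", "One tablet mane",
        "28", "2015-05-02", "", "Dr Brown", "R002", "H01 West Wing"),
    med("ZZ9999", "mystery elixir", "One tablet mane", "28", "2015-05-01",
        "", "Dr Brown", "R003", "H01 East Wing"),
    med(code_of("diazepam"), "diazepam 5 mg tablet", "One tablet mane",
        "28", "2015-01-01", "2015-03-01", "Dr Brown", "R002",
        "H01 West Wing"),
    med(code_of("metformin"), "metformin 500 mg tablet", "One tablet bd",
        "56", "2015-05-01", "", "Dr Quinn", "R004", "Unknown Annex")
  )
  writeLines(lines, path)
  path
}

mini_registry <- function() list(H01 = c("H01 East Wing", "H01 West Wing"))

# fully assembled + enriched state over the mini export
mini_state <- function() {
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path))
  write_mini_export(path)
  parsed <- read_export(path)
  wa <- link_wings(unique(c(parsed$residents$wing_name,
                            parsed$rows$wing_name)), mini_registry())
  snap <- assemble_upload(parsed, wa, "2015-07-01", "test-key",
                          pharmacy_id = "P01")
  snap <- enrich_snapshot(snap, fixture_bundle())
  new_state(snap, fixture_bundle())
}

# ---------------------------------------------------------------------------
# Oracle 1: terminology resolution by brute-force path enumeration.
# Follows every edge from the mapped target upward and collects every MPUU
# reachable by any path; resolution is correct iff exactly one is reached
# and resolve_to_mpuu returns it.
oracle_resolve <- function(vendor, vendor_code, bundle) {
  vm <- bundle$vendor_map
  hit <- vm$vendor == vendor & vm$vendor_code == vendor_code
  if (!any(hit)) return(NA_real_)
  kind_of <- stats::setNames(bundle$concepts$kind,
                             as.character(bundle$concepts$concept_id))
  found <- character()
  frontier <- as.character(vm$target_concept_id[hit][1])
  while (length(frontier)) {
    mpuu <- frontier[kind_of[frontier] == "MPUU"]
    found <- c(found, mpuu)
    up <- as.character(bundle$edges$parent_id[
      as.character(bundle$edges$child_id) %in% frontier])
    frontier <- unique(up)
  }
  found <- unique(found)
  if (length(found) != 1) stop("oracle: ambiguous or absent MPUU")
  as.numeric(found)
}

# Oracle 2: ATC classification by brute-force longest-prefix over the union
# of inclusion and exclusion prefixes.
oracle_classify <- function(code, rules = default_sedative_rules()) {
  prefixes <- c(rules$include$prefix, rules$exclude)
  labels <- c(rules$include$class, rep("NONE", length(rules$exclude)))
  m <- startsWith(code, prefixes)
  if (!any(m)) return("NONE")
  labels[m][which.max(nchar(prefixes[m]))]
}

# ---------------------------------------------------------------------------
# random small-but-valid hierarchy generator for the resolution property:
# every TPUU has one MPUU parent, every TPP one TPUU parent, every CTPP one
# TPP parent, so every mapped code resolves to exactly one MPUU.
random_hierarchy <- function(seed) {
  set.seed(seed)
  n_mpuu <- sample(2:4, 1)
  next_id <- 0L
  nid <- function() { next_id <<- next_id + 1L; next_id * 7 + 100 }
  rows <- list(); edges <- list(); vmap <- list()
  add_con <- function(id, kind) rows[[length(rows) + 1L]] <<- data.frame(
    concept_id = id, kind = kind, preferred_name = paste0(kind, id),
    strength_value = if (kind %in% c("MPUU", "TPUU")) sample(1:20, 1)
                     else NA_real_,
    strength_unit = if (kind %in% c("MPUU", "TPUU")) "mg" else NA_character_,
    dose_form = "tablet", stringsAsFactors = FALSE)
  add_edge <- function(child, parent, rel) edges[[length(edges) + 1L]] <<-
    data.frame(child_id = child, parent_id = parent, relation = rel,
               stringsAsFactors = FALSE)
  expected <- list()
  for (i in seq_len(n_mpuu)) {
    mpuu <- nid(); add_con(mpuu, "MPUU")
    for (j in seq_len(sample(1:2, 1))) {
      tpuu <- nid(); add_con(tpuu, "TPUU")
      add_edge(tpuu, mpuu, "is_generic_of")
      if (stats::runif(1) < 0.8) {
        code <- sprintf("T%04d", tpuu)
        vmap[[length(vmap) + 1L]] <- data.frame(
          vendor = "v1", vendor_code = code, target_concept_id = tpuu,
          origin = "automatic", equivalent_of_name = NA_character_,
          stringsAsFactors = FALSE)
        expected[[code]] <- mpuu
      }
      if (stats::runif(1) < 0.7) {
        tpp <- nid(); add_con(tpp, "TPP"); add_edge(tpp, tpuu, "contains")
        for (k in seq_len(sample(0:2, 1))) {
          ctpp <- nid(); add_con(ctpp, "CTPP"); add_edge(ctpp, tpp, "contains")
          code <- sprintf("C%04d", ctpp)
          vmap[[length(vmap) + 1L]] <- data.frame(
            vendor = "v1", vendor_code = code, target_concept_id = ctpp,
            origin = "automatic", equivalent_of_name = NA_character_,
            stringsAsFactors = FALSE)
          expected[[code]] <- mpuu
        }
      }
    }
  }
  concepts <- do.call(rbind, rows)
  mpuus <- concepts$concept_id[concepts$kind == "MPUU"]
  atc_map <- data.frame(mpuu_id = mpuus,
                        atc_code = sprintf("N05BA%02d", seq_along(mpuus)),
                        primary = TRUE, stringsAsFactors = FALSE)
  bundle <- terminology_bundle(
    concepts, do.call(rbind, edges),
    if (length(vmap)) do.call(rbind, vmap) else
      data.frame(vendor = character(), vendor_code = character(),
                 target_concept_id = numeric(), origin = character(),
                 equivalent_of_name = character(), stringsAsFactors = FALSE),
    atc_map,
    data.frame(atc_code = atc_map$atc_code, ddd_value = 10, ddd_unit = "mg",
               stringsAsFactors = FALSE))
  list(bundle = bundle, expected = expected)
}
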