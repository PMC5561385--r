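# Concept hierarchy validation, vendor-code resolution, ATC maps and the
# manual-mapping workflow.

mk_concepts <- function() data.frame(
  concept_id = c(1, 2, 3, 4),
  kind = c("MPUU", "TPUU", "TPP", "CTPP"),
  preferred_name = c("drug 5 mg tablet", "BRAND 5 mg tablet",
                     "BRAND 5 mg tablet, 25", "BRAND 5 mg tablet, 25, pack"),
  strength_value = c(5, 5, NA, NA),
  strength_unit = c("mg", "mg", NA, NA),
  dose_form = c("tablet", "tablet", NA, NA),
  stringsAsFactors = FALSE)

mk_edges <- function() data.frame(
  child_id = c(2, 3, 4), parent_id = c(1, 2, 3),
  relation = c("is_generic_of", "contains", "contains"),
  stringsAsFactors = FALSE)

mk_vmap <- function() data.frame(
  vendor = c("v1", "v1"), vendor_code = c("A1", "A2"),
  target_concept_id = c(2, 4), origin = "automatic",
  equivalent_of_name = NA_character_, stringsAsFactors = FALSE)

mk_atc <- function() data.frame(mpuu_id = 1, atc_code = "N05BA01",
                                primary = TRUE, stringsAsFactors = FALSE)

mk_ddd <- function() data.frame(atc_code = "N05BA01", ddd_value = 10,
                                ddd_unit = "mg", stringsAsFactors = FALSE)

mk_bundle <- function(...) {
  args <- list(concepts = mk_concepts(), edges = mk_edges(),
               vendor_map = mk_vmap(), atc_map = mk_atc(), ddd = mk_ddd())
  over <- list(...)
  args[names(over)] <- over
  do.call(terminology_bundle, args)
}

test_that("a well-formed bundle validates and resolves at both map levels", {
  b <- mk_bundle()
  expect_s3_class(b, "sedetl_bundle")
  expect_equal(resolve_to_mpuu("v1", "A1", b), 1)   # TPUU-level map
  expect_equal(resolve_to_mpuu("v1", "A2", b), 1)   # CTPP-level map
  expect_true(is.na(resolve_to_mpuu("v1", "NOPE", b)))
  expect_true(is.na(resolve_to_mpuu("other_vendor", "A1", b)))
})

test_that("bundle validation rejects structural violations", {
  expect_error(mk_bundle(concepts = rbind(mk_concepts(), mk_concepts()[1, ])),
               class = "sedetl_integrity_error")
  # illegal edge between resolution kinds (CTPP directly to TPUU)
  bad_edges <- rbind(mk_edges(),
                     data.frame(child_id = 4, parent_id = 2,
                                relation = "contains"))
  expect_error(mk_bundle(edges = bad_edges),
               class = "sedetl_integrity_error")
  # second MPUU parent for the TPUU
  con2 <- rbind(mk_concepts(),
                data.frame(concept_id = 9, kind = "MPUU",
                           preferred_name = "other", strength_value = 5,
                           strength_unit = "mg", dose_form = "tablet"))
  two_parents <- rbind(mk_edges(),
                       data.frame(child_id = 2, parent_id = 9,
                                  relation = "is_generic_of"))
  expect_error(mk_bundle(concepts = con2, edges = two_parents),
               class = "sedetl_integrity_error")
  # duplicate vendor key
  expect_error(mk_bundle(vendor_map = rbind(mk_vmap(), mk_vmap()[1, ])),
               class = "sedetl_integrity_error")
  # vendor map targeting a non-TPUU/CTPP concept
  vm <- mk_vmap(); vm$target_concept_id[1] <- 1
  expect_error(mk_bundle(vendor_map = vm),
               class = "sedetl_integrity_error")
  # malformed ATC code and duplicate primary assignment
  am <- mk_atc(); am$atc_code <- "05XX"
  expect_error(mk_bundle(atc_map = am), class = "sedetl_integrity_error")
  am2 <- rbind(mk_atc(), data.frame(mpuu_id = 1, atc_code = "N05BA02",
                                    primary = TRUE))
  expect_error(mk_bundle(atc_map = am2), class = "sedetl_integrity_error")
})

test_that("cycle detection rejects a cyclic resolution graph", {
  edges <- data.frame(child_id = c(2, 3, 4, 3),
                      parent_id = c(1, 2, 3, 4),
                      relation = c("is_generic_of", "contains", "contains",
                                   "contains"),
                      stringsAsFactors = FALSE)
  # 3 -> 4 is TPP -> CTPP which is not a resolution pair, so craft a true
  # cycle among resolution kinds instead: CTPP -> TPP -> TPUU and TPUU's
  # "parent" TPP again is impossible by kind; use duplicated TPP ids
  con <- rbind(mk_concepts(),
               data.frame(concept_id = 5, kind = "TPP",
                          preferred_name = "p2", strength_value = NA,
                          strength_unit = NA, dose_form = NA))
  cyc <- data.frame(child_id = c(2, 3, 4, 4),
                    parent_id = c(1, 2, 3, 3),
                    relation = c("is_generic_of", "contains", "contains",
                                 "contains"),
                    stringsAsFactors = FALSE)
  expect_false(sedetl:::has_cycle(mk_edges()))
  self_loop <- data.frame(child_id = 3, parent_id = 3, relation = "contains")
  expect_true(sedetl:::has_cycle(self_loop))
  expect_true(sedetl:::has_cycle(
    data.frame(child_id = c(3, 4), parent_id = c(4, 3),
               relation = "contains")))
  expect_false(sedetl:::has_cycle(cyc))  # parallel edges are not a cycle
  expect_s3_class(mk_bundle(concepts = con), "sedetl_bundle")
})

test_that("atc lookups order primary first and enforce MPUU kind", {
  am <- rbind(data.frame(mpuu_id = 1, atc_code = "N06CA01", primary = FALSE),
              data.frame(mpuu_id = 1, atc_code = "N05BA02", primary = TRUE))
  b <- mk_bundle(atc_map = am)
  expect_equal(atc_codes_for_mpuu(1, b), c("N05BA02", "N06CA01"))
  expect_equal(mpuu_to_atc(1, b), "N05BA02")
  expect_error(atc_codes_for_mpuu(2, b), class = "sedetl_contract_error")
  expect_error(atc_codes_for_mpuu(999, b), class = "sedetl_integrity_error")
  b2 <- mk_bundle(atc_map = mk_atc()[0, ])
  expect_equal(atc_codes_for_mpuu(1, b2), character())
  expect_true(is.na(mpuu_to_atc(1, b2)))
})

test_that("manual mappings append, log, and refuse conflicts", {
  b <- mk_bundle()
  b2 <- add_manual_mapping(b, "v1", "NEW1", 2)
  expect_equal(resolve_to_mpuu("v1", "NEW1", b2), 1)
  le <- attr(b2, "log_entry")
  expect_equal(le$action, "add")
  expect_equal(le$entity_id, "v1:NEW1")
  expect_equal(b2$vendor_map$origin[b2$vendor_map$vendor_code == "NEW1"],
               "manual")
  b3 <- add_manual_mapping(b, "v1", "NEW2", 4,
                           equivalent_of_name = "olde mixture")
  expect_equal(b3$vendor_map$origin[b3$vendor_map$vendor_code == "NEW2"],
               "equivalent_fallback")
  expect_error(add_manual_mapping(b, "v1", "A1", 2),
               class = "sedetl_conflict_error")
  expect_error(add_manual_mapping(b, "v1", "NEW3", 1),
               class = "sedetl_contract_error")
})

test_that("bundles round-trip through the TSV directory format", {
  b <- fixture_bundle()
  dir <- tempfile("bundle")
  write_bundle(b, dir)
  b2 <- read_bundle(dir)
  expect_equal(b2$concepts$concept_id, b$concepts$concept_id)
  expect_equal(b2$edges, b$edges, ignore_attr = TRUE)
  expect_equal(b2$vendor_map$vendor_code, b$vendor_map$vendor_code)
  expect_equal(b2$atc_map, b$atc_map, ignore_attr = TRUE)
  expect_equal(b2$ddd$ddd_value, b$ddd$ddd_value)
  cat <- fixture_catalogue()
  expect_equal(resolve_to_mpuu("alpha_pack", code_of("diazepam"), b2),
               cat$mpuu_id[cat$drug == "diazepam"])
  unlink(dir, recursive = TRUE)
})

test_that("list_unmapped aggregates by descending occurrence count", {
  meds <- data.frame(
    vendor = "v1", vendor_med_id = c("Z1", "Z2", "Z2", "A1"),
    med_name = c("zed one", "zed two", "zed two", "mapped"),
    mpuu_id = c(NA, NA, NA, 1),
    stringsAsFactors = FALSE)
  um <- list_unmapped(meds)
  expect_equal(um$vendor_code, c("Z2", "Z1"))
  expect_equal(um$n, c(2L, 1L))
  expect_error(list_unmapped(data.frame(vendor = "v")),
               class = "sedetl_contract_error")
  none <- list_unmapped(meds[4, , drop = FALSE])
  expect_equal(nrow(none), 0L)
})
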