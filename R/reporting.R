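# Audit outputs: per-home prevalence, coverage/accuracy statistics, the
# pooled two-proportion z-test, and interaction session-time estimates.

#' Per-home prevalence and sedative-load report
#'
#' Computed over current (non-merged, non-deleted) residents of a verified
#' home. A resident counts once per class regardless of how many drugs of
#' that class they take; regular and PRN use are reported separately. Mean
#' loads are per-resident means of the diazepam / chlorpromazine equivalent
#' daily doses over all residents of the home (zero for residents without
#' regular sedatives).
#'
#' @param state a `sedetl_state`.
#' @param home_id home to report on.
#' @param ddd_table DDD reference table (defaults to the bundle's).
#' @param equivalents optional equivalence override table.
#' @param require_verified gate on [verify_home()] status (default `TRUE`).
#' @return one-row data frame (`sedetl_prevalence`).
#' @export
prevalence_report <- function(state, home_id, ddd_table = NULL,
                              equivalents = NULL, require_verified = TRUE) {
  ddd_table <- ddd_table %||% state$bundle$ddd
  if (require_verified && verify_home(state, home_id) != "VERIFIED")
    stop_gating(sprintf(
      "home %s is not verified; audit reports unlock after in-home verification",
      home_id))
  res <- active_residents(state)
  res <- res[res$home_id == home_id, , drop = FALSE]
  meds <- active_medications(state)
  meds <- meds[meds$home_id == home_id & meds$resident_id %in% res$resident_id, ,
               drop = FALSE]
  n <- nrow(res)
  on_class <- function(cls, prn) {
    sel <- meds$class == cls & meds$prn == prn
    length(unique(meds$resident_id[sel]))
  }
  loads <- do.call(rbind, lapply(res$resident_id, function(rid)
    resident_load(meds[meds$resident_id == rid, , drop = FALSE],
                  ddd_table, equivalents)))
  structure(data.frame(
    home_id = home_id,
    snapshot_label = state$snapshot_label,
    n_residents = n,
    pct_on_antipsychotic_regular = pct(on_class("ANTIPSYCHOTIC", FALSE), n),
    pct_on_benzodiazepine_regular = pct(on_class("BENZODIAZEPINE", FALSE), n),
    pct_on_antipsychotic_prn = pct(on_class("ANTIPSYCHOTIC", TRUE), n),
    pct_on_benzodiazepine_prn = pct(on_class("BENZODIAZEPINE", TRUE), n),
    mean_diazepam_equiv_mg =
      if (n) mean(loads$benzodiazepine_diazepam_equiv_mg_per_day) else NA_real_,
    mean_chlorpromazine_equiv_mg =
      if (n) mean(loads$antipsychotic_chlorpromazine_equiv_mg_per_day) else NA_real_,
    stringsAsFactors = FALSE), class = c("sedetl_prevalence", "data.frame"))
}

#' Upload coverage and correction-share statistics
#'
#' From the counts of sedative records extracted automatically, added
#' manually, and modified during validation:
#' identified share = 100 e / (e + a), modified share = 100 m / e,
#' added share = 100 a / (e + a); all at 2 decimal places, half away from
#' zero. Undefined shares (zero denominator) are `NA`.
#'
#' @param extracted number of records captured by automatic extraction.
#' @param added number of records added manually during validation.
#' @param modified number of extracted records modified during validation.
#' @return one-row data frame with the counts and derived percentages.
#' @export
coverage_stats <- function(extracted, added, modified) {
  stopifnot(extracted >= 0, added >= 0, modified >= 0)
  total <- extracted + added
  data.frame(
    extracted = extracted, added = added, modified = modified,
    identified_pct = pct(extracted, total),
    modified_pct = pct(modified, extracted),
    added_pct = pct(added, total),
    stringsAsFactors = FALSE)
}

#' Pooled two-proportion z-test
#'
#' Normal-approximation test without continuity correction:
#' `z = (p1 - p2) / sqrt(p(1 - p)(1/n1 + 1/n2))` with the pooled proportion
#' `p = (x1 + x2) / (n1 + n2)`; the two-tailed p-value comes from the
#' standard normal distribution. A degenerate pooled proportion (0 or 1)
#' leaves z undefined (`NA`) with p = 1.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return list of class `sedetl_ztest`: `z`, `p_two_tailed`, `p1`, `p2`,
#'   `pooled_p`.
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp == 0 || pp == 1) {
    z <- NA_real_
    p <- 1
  } else {
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(z = z, p_two_tailed = p, p1 = p1, p2 = p2, pooled_p = pp),
            class = "sedetl_ztest")
}

#' @export
print.sedetl_ztest <- function(x, ...) {
  cat(sprintf("Two-proportion z-test: z = %.2f, two-tailed p %s\n",
              x$z, if (x$p_two_tailed < 0.001) "< .001"
                   else sprintf("= %.3f", x$p_two_tailed)))
  cat(sprintf("  p1 = %.4f, p2 = %.4f, pooled = %.4f\n", x$p1, x$p2,
              x$pooled_p))
  invisible(x)
}

#' Estimate interaction time from website event streams
#'
#' Aggregates continuous blocks of interaction events: events by the same
#' actor at the same home separated by at most `gap_threshold_min` minutes
#' belong to one block; a block's duration is last minus first event (a lone
#' event is a zero-minute block). Totals are summed per (actor, home), and
#' divided by the home's resident count when supplied.
#'
#' @param events data frame with columns `actor`, `home_id`, `timestamp`
#'   (POSIXct or ISO 8601 strings).
#' @param gap_threshold_min maximum within-block gap, minutes (default 10).
#' @param resident_counts optional named vector `home_id -> n residents`.
#' @return data frame `actor`, `home_id`, `minutes`, `n_blocks`, and
#'   `seconds_per_resident` when counts are given.
#' @export
session_time_estimate <- function(events, gap_threshold_min = 10,
                                  resident_counts = NULL) {
  ts <- events$timestamp
  if (!inherits(ts, "POSIXct"))
    ts <- as.POSIXct(sub("T", " ", as.character(ts), fixed = TRUE),
                     tz = "UTC")
  key <- interaction(events$actor, events$home_id, drop = TRUE)
  parts <- split(seq_len(nrow(events)), key)
  out <- do.call(rbind, lapply(parts, function(idx) {
    t <- sort(ts[idx])
    gaps <- as.numeric(difftime(t[-1], t[-length(t)], units = "mins"))
    block_id <- cumsum(c(0, gaps > gap_threshold_min))
    mins <- sum(vapply(split(t, block_id), function(b)
      as.numeric(difftime(max(b), min(b), units = "mins")), 0.0))
    data.frame(actor = events$actor[idx[1]], home_id = events$home_id[idx[1]],
               minutes = mins, n_blocks = length(unique(block_id)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(resident_counts)) {
    out$seconds_per_resident <-
      60 * out$minutes / as.numeric(resident_counts[out$home_id])
  }
  out
}
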