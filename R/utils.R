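#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used for all printed percentages in audit reports (base R's
#' `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage of a count over a denominator, at printed precision
#'
#' @param num numerator count.
#' @param den denominator count.
#' @param digits decimal places (default 2).
#' @return numeric percentage, `NA` when the denominator is zero.
#' @export
pct <- function(num, den, digits = 2) {
  out <- round_half_away(100 * num / den, digits)
  out[rep_len(den == 0, length(out))] <- NA_real_
  out
}

# condition constructors: every operational failure carries a subclass so
# callers (and the CLI) can map error kinds to exit codes
stop_sedetl <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "sedetl_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stop_integrity <- function(msg, ...) stop_sedetl(msg, "sedetl_integrity_error", ...)
stop_format    <- function(msg, ...) stop_sedetl(msg, "sedetl_format_error", ...)
stop_gating    <- function(msg, ...) stop_sedetl(msg, "sedetl_gating_error", ...)
stop_conflict  <- function(msg, ...) stop_sedetl(msg, "sedetl_conflict_error", ...)
stop_contract  <- function(msg, ...) stop_sedetl(msg, "sedetl_contract_error", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# empty-safe character coercion for log field values
as_chr <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x)) NA_character_ else as.character(x)
}

read_tsv_file <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = NA, na.strings = c("NA", ""), quote = "",
                    comment.char = "")
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
}
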