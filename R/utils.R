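# Shared helpers: condition classes, ISO-8601 millisecond timestamps.

amo_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "amo_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

amo_config_error   <- function(msg) amo_stop(msg, "amo_config_error")
amo_data_error     <- function(msg) amo_stop(msg, "amo_data_error")
amo_parse_error    <- function(msg) amo_stop(msg, c("amo_parse_error", "amo_data_error"))
amo_protocol_error <- function(msg) amo_stop(msg, "amo_protocol_error")

#' Format timestamps as ISO-8601 UTC with millisecond precision
#'
#' Timestamps are rounded to the nearest millisecond before formatting, so
#' formatting is exact and stable under write/read/write cycles.
#'
#' @param t `POSIXct` vector.
#' @return Character vector like `"2026-01-05T12:00:00.050Z"`.
#' @export
format_iso_ms <- function(t) {
  stopifnot(inherits(t, "POSIXct"))
  ms_total <- round(as.numeric(t) * 1000)
  secs <- floor(ms_total / 1000)
  ms <- ms_total - secs * 1000
  base <- format(as.POSIXct(secs, origin = "1970-01-01", tz = "UTC"),
                 "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out <- sprintf("%s.%03dZ", base, as.integer(ms))
  out[is.na(t)] <- NA_character_
  out
}

#' Parse ISO-8601 UTC timestamps with fractional seconds
#'
#' @param s Character vector as produced by [format_iso_ms()].
#' @return `POSIXct` (UTC).
#' @export
parse_iso_ms <- function(s) {
  out <- as.POSIXct(sub("Z$", "", s), format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  bad <- !is.na(s) & is.na(out)
  if (any(bad)) {
    amo_parse_error(sprintf("unparseable timestamp(s), e.g. '%s'", s[bad][1]))
  }
  out
}

# Numbers serialized with enough digits to reparse exactly.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

epoch_ct <- function(x) as.POSIXct(x, origin = "1970-01-01", tz = "UTC")
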