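#' Warning codes used to flag irregular pings
#'
#' Stable identifiers persisted in the store: `DUPLICATE`, `ON_LAND`,
#' `BAD_SPEED`, `BAD_HEADING`, `IN_HARBOUR`, `NOT_COHERENT`, `OUT_OF_RANGE`.
#' A ping may carry several codes; they are kept in the `flags` column as a
#' comma-separated string ("" when clean).
#'
#' @return Character vector of the recognised codes.
#' @export
warning_codes <- function() {
  c("DUPLICATE", "ON_LAND", "BAD_SPEED", "BAD_HEADING",
    "IN_HARBOUR", "NOT_COHERENT", "OUT_OF_RANGE")
}

#' Test whether pings carry a warning code
#' @param pings Ping data frame.
#' @param code One code from [warning_codes()].
#' @return Logical vector.
#' @export
has_flag <- function(pings, code) {
  stopifnot(code %in% warning_codes())
  grepl(paste0("(^|,)", code, "(,|$)"), pings$flags)
}

# Add `code` to flags of rows selected by `which` (idempotent).
add_flag <- function(flags, code, which) {
  sel <- which & !grepl(paste0("(^|,)", code, "(,|$)"), flags)
  flags[sel] <- ifelse(flags[sel] == "", code, paste0(flags[sel], ",", code))
  flags
}

#' Tally pings per warning code
#' @param pings Ping data frame.
#' @return Named integer vector, one entry per code, in [warning_codes()] order.
#' @export
flag_counts <- function(pings) {
  vapply(warning_codes(), function(cd) sum(has_flag(pings, cd)), integer(1))
}
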