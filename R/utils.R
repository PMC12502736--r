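# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; report tables in pharmacovigilance
#' papers conventionally round half up, so percentages are formatted with
#' this rule.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Pad a possibly partial numeric date string (YYYY, YYYYMM or YYYYMMDD) to
# the earliest full date it could denote, returned as an integer for
# ordering. NA / empty -> NA.
pad_partial_date <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x)] <- NA_character_
  n <- nchar(x)
  out <- rep(NA_real_, length(x))
  ok4 <- !is.na(x) & n == 4L
  ok6 <- !is.na(x) & n == 6L
  ok8 <- !is.na(x) & n == 8L
  out[ok4] <- as.numeric(x[ok4]) * 10000 + 101
  out[ok6] <- as.numeric(x[ok6]) * 100 + 1
  out[ok8] <- as.numeric(x[ok8])
  out
}

# TRUE where x is a complete (8-digit) parseable date string.
is_complete_date <- function(x) {
  x <- trimws(as.character(x))
  !is.na(x) & nchar(x) == 8L & !is.na(suppressWarnings(as.numeric(x)))
}

# Convert complete YYYYMMDD strings to Date (NA elsewhere).
yyyymmdd_to_date <- function(x) {
  out <- rep(as.Date(NA), length(x))
  ok <- is_complete_date(x)
  out[ok] <- as.Date(as.character(x[ok]), format = "%Y%m%d")
  out
}

date_to_yyyymmdd <- function(d) format(d, "%Y%m%d")

# Case/whitespace-insensitive key used for drug and PT matching.
fold_name <- function(x) tolower(gsub("\\s+", " ", trimws(as.character(x))))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}
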