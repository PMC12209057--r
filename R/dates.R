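#' Parse claims-database date strings
#'
#' Japanese claims extracts store some dates (birth month, observation start
#' and stop, outpatient visit dates) at year-month resolution as six-digit
#' `YYYYMM` strings; other dates carry full eight-digit `YYYYMMDD` precision.
#' Year-month dates are completed to day resolution with the conventional
#' imputed day of month, 15, so that e.g. `"202208"` parses to 2022-08-15
#' while `"20220815"` parses literally.
#'
#' @param raw character vector of 6- or 8-digit date strings (numeric input
#'   is accepted and coerced). `NA` propagates.
#' @param imputed_day day of month substituted for 6-digit inputs (default 15).
#' @return a `Date` vector, always at day resolution.
#' @examples
#' parse_claim_date(c("202208", "20220815"))
#' @export
parse_claim_date <- function(raw, imputed_day = 15L) {
  if (length(raw) == 0L) return(as.Date(character()))
  raw <- as.character(raw)
  out <- rep(as.Date(NA), length(raw))
  ok_na <- is.na(raw)
  six <- !ok_na & grepl("^[0-9]{6}$", raw)
  eight <- !ok_na & grepl("^[0-9]{8}$", raw)
  bad <- !ok_na & !six & !eight
  if (any(bad)) {
    stop("malformed claim date(s): ",
         paste(utils::head(unique(raw[bad]), 5L), collapse = ", "),
         " (expected 6-digit YYYYMM or 8-digit YYYYMMDD)")
  }
  expanded <- raw
  expanded[six] <- paste0(raw[six], sprintf("%02d", as.integer(imputed_day)))
  mm <- as.integer(substr(expanded[!ok_na], 5L, 6L))
  if (any(mm < 1L | mm > 12L)) {
    off <- raw[!ok_na][mm < 1L | mm > 12L]
    stop("month out of range in claim date(s): ",
         paste(utils::head(unique(off), 5L), collapse = ", "))
  }
  parsed <- as.Date(expanded[!ok_na], format = "%Y%m%d")
  if (anyNA(parsed)) {
    off <- raw[!ok_na][is.na(parsed)]
    stop("invalid day of month in claim date(s): ",
         paste(utils::head(unique(off), 5L), collapse = ", "))
  }
  yy <- as.integer(format(parsed, "%Y"))
  if (any(yy < 1900L | yy > 2100L)) {
    off <- raw[!ok_na][yy < 1900L | yy > 2100L]
    stop("claim date(s) outside supported range 1900-2100: ",
         paste(utils::head(unique(off), 5L), collapse = ", "))
  }
  out[!ok_na] <- parsed
  out
}

#' Render a Date as an 8-digit claims date string
#'
#' Inverse of [parse_claim_date()] for day-resolution dates; parsing the
#' result reproduces the input exactly.
#'
#' @param x a `Date` vector.
#' @return character vector of `YYYYMMDD` strings.
#' @export
format_claim_date <- function(x) {
  format(as.Date(x), "%Y%m%d")
}

# year-month string (YYYYMM) for month-resolution fields such as birth_ym
format_claim_ym <- function(x) {
  format(as.Date(x), "%Y%m")
}
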