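# FAERS dates come as 4- (year), 6- (year-month) or 8-digit (full) strings.
# They are kept as strings in the parsed tables; these helpers interpret them.

#' Parse FAERS partial date strings
#'
#' FAERS serialises dates as `YYYY`, `YYYYMM` or `YYYYMMDD`. Anything else
#' (empty, non-digit, calendar-invalid, year outside 1900--2100) is treated as
#' missing. The function is total: it never throws on malformed input.
#'
#' @param raw character vector of raw date fields.
#' @return a `data.table` with one row per input and columns `year`, `month`,
#'   `day` (integer, `NA` when absent) and `precision` (`"Y"`, `"YM"`,
#'   `"YMD"`, or `NA` for missing).
#' @export
#' @examples
#' parse_partial_date(c("20200301", "202003", "2020", "", "20200230"))
parse_partial_date <- function(raw) {
  raw <- as.character(raw)
  n <- length(raw)
  out <- data.table(
    year = rep(NA_integer_, n), month = rep(NA_integer_, n),
    day = rep(NA_integer_, n), precision = rep(NA_character_, n)
  )
  x <- trimws(raw)
  x[is.na(x)] <- ""
  digits <- grepl("^[0-9]+$", x)

  y4 <- digits & nchar(x) == 4L
  out$year[y4] <- as.integer(x[y4])
  out$precision[y4] <- "Y"

  y6 <- digits & nchar(x) == 6L
  out$year[y6] <- as.integer(substr(x[y6], 1L, 4L))
  out$month[y6] <- as.integer(substr(x[y6], 5L, 6L))
  out$precision[y6] <- "YM"

  y8 <- digits & nchar(x) == 8L
  out$year[y8] <- as.integer(substr(x[y8], 1L, 4L))
  out$month[y8] <- as.integer(substr(x[y8], 5L, 6L))
  out$day[y8] <- as.integer(substr(x[y8], 7L, 8L))
  out$precision[y8] <- "YMD"

  # sanity: plausible year, valid month; valid calendar day for YMD
  bad <- !is.na(out$year) & (out$year < 1900L | out$year > 2100L)
  bad <- bad | (!is.na(out$month) & (out$month < 1L | out$month > 12L))
  ymd <- !is.na(out$precision) & out$precision == "YMD" & !bad
  if (any(ymd)) {
    d <- as.Date(x[ymd], format = "%Y%m%d")
    bad[which(ymd)[is.na(d)]] <- TRUE
  }
  out$year[bad] <- NA_integer_
  out$month[bad] <- NA_integer_
  out$day[bad] <- NA_integer_
  out$precision[bad] <- NA_character_
  out[]
}

#' Sortable integer key for a partial date (missing parts count as 0)
#'
#' Gives the deterministic total order used for "highest FDA_DT": compare by
#' (year, month-or-0, day-or-0). Missing dates map to `NA`.
#'
#' @param raw character vector of raw date fields.
#' @return integer vector `year*10000 + month*100 + day`.
#' @export
partial_date_key <- function(raw) {
  p <- parse_partial_date(raw)
  ifelse(is.na(p$year), NA_integer_,
         p$year * 10000L +
           data.table::fifelse(is.na(p$month), 0L, p$month) * 100L +
           data.table::fifelse(is.na(p$day), 0L, p$day))
}

#' Convert full-precision (8-digit) date strings to Date, else NA
#' @noRd
full_date <- function(raw) {
  p <- parse_partial_date(raw)
  out <- rep(as.Date(NA), length(raw))
  ok <- !is.na(p$precision) & p$precision == "YMD"
  if (any(ok)) {
    out[ok] <- as.Date(sprintf("%04d-%02d-%02d", p$year[ok], p$month[ok], p$day[ok]))
  }
  out
}

#' Serialise a Date back to the 8-digit FAERS form
#' @noRd
format_faers_date <- function(d) {
  out <- format(d, "%Y%m%d")
  out[is.na(out)] <- ""
  out
}
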