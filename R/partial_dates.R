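# FAERS dates are plain digit strings: CCYYMMDD, CCYYMM, or CCYY, and are
# frequently truncated or absent. They are carried as "partial dates": a
# year/month/day triple plus a precision level, so downstream rules
# (onset intervals, windows) can insist on full-day precision explicitly.

#' Parse FAERS digit-string dates into partial dates
#'
#' Total function: any token that is not a valid 8/6/4-digit date collapses
#' to `precision = "none"` rather than erroring. Impossible calendar dates
#' (month 13, Feb 30, ...) also map to `"none"`.
#'
#' @param token character vector of raw date tokens (`"20190301"`, `"201903"`,
#'   `"2019"`, `""`, `NA`)
#' @return data.table with columns `year`, `month`, `day` (integer, NA when
#'   absent) and `precision` (`"day"`, `"month"`, `"year"`, `"none"`)
#' @export
#' @examples
#' parse_partial_date(c("20190301", "201903", "2019", "20191341", ""))
parse_partial_date <- function(token) {
  token <- trimws(as.character(token))
  token[is.na(token)] <- ""
  n <- length(token)
  year <- month <- day <- rep(NA_integer_, n)
  precision <- rep("none", n)

  digits <- grepl("^[0-9]+$", token)
  d8 <- digits & nchar(token) == 8L
  d6 <- digits & nchar(token) == 6L
  d4 <- digits & nchar(token) == 4L

  year[d8 | d6 | d4] <- as.integer(substr(token[d8 | d6 | d4], 1L, 4L))
  month[d8 | d6] <- as.integer(substr(token[d8 | d6], 5L, 6L))
  day[d8] <- as.integer(substr(token[d8], 7L, 8L))
  precision[d4] <- "year"
  precision[d6] <- "month"
  precision[d8] <- "day"

  # month validity
  bad_m <- precision %in% c("month", "day") & (month < 1L | month > 12L)
  # day validity through Date round-trip (handles month lengths, leap years)
  chk <- precision == "day" & !bad_m
  if (any(chk)) {
    dt <- as.Date(sprintf("%04d-%02d-%02d", year[chk], month[chk], day[chk]),
                  format = "%Y-%m-%d")
    bad_d <- is.na(dt)
    idx <- which(chk)[bad_d]
    bad_m[idx] <- TRUE
  }
  year[bad_m] <- NA_integer_; month[bad_m] <- NA_integer_
  day[bad_m] <- NA_integer_; precision[bad_m] <- "none"
  # month precision keeps day absent by construction; enforce year precision
  month[precision == "year"] <- NA_integer_
  day[precision %in% c("year", "month")] <- NA_integer_

  data.table::data.table(year = year, month = month, day = day,
                         precision = precision)
}

#' Format partial dates back to FAERS digit strings
#'
#' Right inverse of [parse_partial_date()]: formatting then parsing is the
#' identity on valid partial dates; `precision = "none"` formats to `""`.
#'
#' @param pd data.table as returned by [parse_partial_date()]
#' @return character vector of digit tokens
#' @export
format_partial_date <- function(pd) {
  out <- character(nrow(pd))
  i <- pd$precision == "year"
  out[i] <- sprintf("%04d", pd$year[i])
  i <- pd$precision == "month"
  out[i] <- sprintf("%04d%02d", pd$year[i], pd$month[i])
  i <- pd$precision == "day"
  out[i] <- sprintf("%04d%02d%02d", pd$year[i], pd$month[i], pd$day[i])
  out
}

# Internal: Date vector for day-precision entries, NA otherwise.
partial_date_as_date <- function(pd) {
  out <- rep(as.Date(NA), nrow(pd))
  i <- pd$precision == "day"
  if (any(i)) {
    out[i] <- as.Date(sprintf("%04d-%02d-%02d", pd$year[i], pd$month[i],
                              pd$day[i]))
  }
  out
}

# Internal: sortable numeric key (CCYYMMDD with 0 for missing parts);
# used for latest-FDA_DT dedup where partial dates still order coarsely.
partial_date_key <- function(token) {
  token <- trimws(as.character(token))
  token[is.na(token) | !grepl("^[0-9]+$", token)] <- "0"
  as.numeric(substr(paste0(token, "00000000"), 1L, 8L))
}

#' Quarter label for a partial date
#'
#' @param pd partial-date table
#' @return character vector like `"2019Q3"`; NA when the year or month is
#'   unavailable
#' @export
partial_date_quarter <- function(pd) {
  ifelse(pd$precision %in% c("month", "day"),
         sprintf("%04dQ%d", pd$year, (pd$month - 1L) %/% 3L + 1L),
         NA_character_)
}
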