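#' @import data.table
#' @importFrom stats median quantile rbinom rlnorm rmultinom runif rnorm
#'   pchisq pnorm qnorm setNames aggregate fivenum binomial plogis
#' @importFrom utils head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Decimal rounding with the half-up tie rule used when formatting
#' percentage cells, so that e.g. 30.45 renders as 30.5 rather than
#' banker's-rounded 30.4.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a count over a denominator, half-up rounded
#' @param n numerator count
#' @param denom denominator count
#' @param digits decimal places (default 1, matching report tables)
#' @return percentage; NA when denom is 0
#' @export
pct <- function(n, denom, digits = 1) {
  denom <- rep_len(denom, length(n))
  out <- rep(NA_real_, length(n))
  ok <- !is.na(denom) & denom > 0
  out[ok] <- round_half_up(100 * n[ok] / denom[ok], digits)
  out
}

# Internal: empty rejects log with a stable column order. ("key" is the
# report key of the rejected row; built via setnames because data.table()
# reserves the name `key` for its own argument.)
empty_rejects <- function() {
  out <- data.table::data.table(
    table_name = character(), report_key = character(),
    reason = character(), detail = character()
  )
  data.table::setnames(out, "report_key", "key")
  out
}

# Internal: append a block of reject entries; both are data.tables.
add_rejects <- function(log, table_name, key, reason, detail = "") {
  if (length(key) == 0L) return(log)
  entry <- data.table::data.table(
    table_name = table_name, report_key = as.character(key),
    reason = reason, detail = detail
  )
  data.table::setnames(entry, "report_key", "key")
  rbind(log, entry)
}

#' Write a rejects log sidecar file
#'
#' Rejected input rows are never silently dropped; they are written to a
#' TSV sidecar so report-count figures remain auditable.
#'
#' @param rejects rejects data.table (as attached to parsed archives)
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_rejects <- function(rejects, path) {
  data.table::fwrite(rejects, path, sep = "\t")
  invisible(path)
}
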