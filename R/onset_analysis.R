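# Time-to-onset analysis: onset = event date minus therapy start date, in
# whole days, computed only when both dates are complete and the interval
# is non-negative (input-error reports are excluded, with the reason
# recorded). Distributions are summarised by fixed bins and median/IQR and
# compared with rank tests.

ONSET_BIN_LABELS <- c("0-30d", "31-60d", "61-90d", "91-180d", "181-365d",
                      ">365d")
ONSET_BIN_UPPER <- c(30, 60, 90, 180, 365, Inf)

#' Time to onset from raw date tokens
#'
#' Vectorised: returns the day count when both dates have full day
#' precision and the event does not precede the start; otherwise the row
#' is excluded with a reason (`missing` when either date is absent or
#' unparseable, `partial_precision` when truncated to month/year,
#' `negative_interval` when the event precedes the start).
#'
#' @param event_tok raw EVENT_DT tokens
#' @param start_tok raw therapy START_DT tokens
#' @return data.table `(days, excluded)`; exactly one of the two is
#'   non-NA per row
#' @export
onset_interval <- function(event_tok, start_tok) {
  ev <- parse_partial_date(event_tok)
  st <- parse_partial_date(start_tok)
  n <- nrow(ev)
  days <- rep(NA_integer_, n)
  excluded <- rep(NA_character_, n)

  miss <- ev$precision == "none" | st$precision == "none"
  part <- !miss & (ev$precision != "day" | st$precision != "day")
  full <- !miss & !part
  excluded[miss] <- "missing"
  excluded[part] <- "partial_precision"
  if (any(full)) {
    idx <- which(full)
    d <- as.integer(partial_date_as_date(ev)[idx] -
                      partial_date_as_date(st)[idx])
    neg <- d < 0L
    days[idx[!neg]] <- d[!neg]
    excluded[idx[neg]] <- "negative_interval"
  }
  data.table::data.table(days = days, excluded = excluded)
}

#' Bin onset days into the reporting intervals
#'
#' Closed integer bins: 0-30, 31-60, 61-90, 91-180, 181-365, >365 days.
#'
#' @param days non-negative integer vector
#' @return factor with the six bin labels
#' @export
bin_onset <- function(days) {
  stopifnot(all(days >= 0, na.rm = TRUE))
  idx <- findInterval(days, c(0, ONSET_BIN_UPPER[-length(ONSET_BIN_UPPER)] + 1))
  factor(ONSET_BIN_LABELS[idx], levels = ONSET_BIN_LABELS)
}

#' Median and interquartile range
#'
#' Median by the midpoint-of-middle-two convention. Quartiles default to
#' the linear-interpolation convention (the standard type-7 sample
#' quantile); `type = "tukey"` switches to Tukey's inclusive hinges.
#'
#' @param days numeric vector
#' @param type `"linear"` (default) or `"tukey"`
#' @return list `(n, median, q1, q3)`; all NA for an empty vector
#' @export
median_iqr <- function(days, type = c("linear", "tukey")) {
  type <- match.arg(type)
  days <- days[!is.na(days)]
  if (length(days) == 0L) {
    return(list(n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  }
  if (type == "linear") {
    q <- unname(quantile(days, c(0.25, 0.75), type = 7))
  } else {
    f <- fivenum(days)
    q <- f[c(2L, 4L)]
  }
  list(n = length(days), median = unname(median(days)), q1 = q[[1L]],
       q3 = q[[2L]])
}

# Internal: midranks of a pooled sample plus the tie-size table.
midranks <- function(v) {
  r <- rank(v, ties.method = "average")
  list(ranks = r, ties = as.numeric(table(v)))
}

#' Mann-Whitney U test
#'
#' U counts pairs (x, y) with x > y (ties 1/2), i.e. U = R_x - n_x(n_x+1)/2
#' from midrank sums. For group sizes both at most `exact_max`, the
#' two-sided p-value is computed by exact enumeration of all rank
#' assignments (conditional on the observed ties); otherwise by normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y numeric vectors, both non-empty
#' @param exact_max size threshold for exact enumeration (default 8)
#' @return list `(statistic, p_value, n_per_group, tie_corrected, method)`
#' @export
mann_whitney <- function(x, y, exact_max = 8L) {
  stopifnot(length(x) > 0L, length(y) > 0L)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  mr <- midranks(pooled)
  U <- sum(mr$ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(mr$ties > 1)

  if (all(pooled == pooled[[1L]])) {
    return(list(statistic = U, p_value = 1.0, n_per_group = c(n1, n2),
                tie_corrected = ties, method = "degenerate"))
  }

  if (n1 <= exact_max && n2 <= exact_max) {
    combos <- utils::combn(N, n1)
    u_all <- colSums(matrix(mr$ranks[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tiecorr <- sum(mr$ties^3 - mr$ties) / (N * (N - 1))
    v <- n1 * n2 / 12 * ((N + 1) - tiecorr)
    if (v <= 0) {
      p <- 1.0
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(v)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  list(statistic = U, p_value = p, n_per_group = c(n1, n2),
       tie_corrected = ties, method = method)
}

#' Kruskal-Wallis rank test
#'
#' H from midranks with the tie-correction divisor
#' 1 - sum(t^3 - t) / (N^3 - N); p-value from the chi-square tail with
#' k - 1 degrees of freedom.
#'
#' @param groups named list of non-empty numeric vectors (k >= 2)
#' @return list `(statistic, df, p_value, n_per_group, tie_corrected)`
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2L)
  nm <- names(groups) %||% as.character(seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes == 0L)) {
    stop("empty group in kruskal_wallis: ",
         paste(nm[sizes == 0L], collapse = ", "))
  }
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  mr <- midranks(pooled)
  grp <- rep(seq_along(groups), sizes)
  rbar <- tapply(mr$ranks, grp, mean)
  H <- 12 / (N * (N + 1)) * sum(sizes * (rbar - (N + 1) / 2)^2)
  corr <- 1 - sum(mr$ties^3 - mr$ties) / (N^3 - N)
  H <- if (corr > 0) H / corr else 0
  df <- length(groups) - 1L
  p <- if (H == 0) 1.0 else pchisq(H, df, lower.tail = FALSE)
  list(statistic = H, df = df, p_value = p,
       n_per_group = as.integer(sizes),
       tie_corrected = any(mr$ties > 1))
}

#' Empirical cumulative incidence of onset times
#'
#' Per group, the percent of that group's observed events occurring by
#' each observed day: a nondecreasing step function ending at 100%. This
#' is an empirical CDF of observed events, not a survival estimate (no
#' censoring model).
#'
#' @param samples named list of non-empty day vectors
#' @return data.table `(group, day, cum_n, cum_pct)`
#' @export
cumulative_incidence <- function(samples) {
  stopifnot(length(samples) >= 1L, all(lengths(samples) > 0L))
  nm <- names(samples) %||% as.character(seq_along(samples))
  pieces <- lapply(seq_along(samples), function(i) {
    d <- sort(samples[[i]])
    ud <- unique(d)
    cn <- cumsum(tabulate(match(d, ud)))
    data.table::data.table(group = nm[[i]], day = ud, cum_n = cn,
                           cum_pct = 100 * cn / length(d))
  })
  data.table::rbindlist(pieces)
}
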