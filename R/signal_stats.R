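# Disproportionality statistics. Each drug-event pair is summarised by the
# 2x2 report table
#
#                 event     other events
#   target drug     a            b
#   other drugs     c            d
#
# and assessed with the reporting odds ratio ROR = ad/bc (Haldane-Anscombe
# 0.5 correction only when a cell is zero) and the shrinkage-based
# information component IC = log2((a + 0.5) / (E + 0.5)), E = (a+b)(a+c)/N.
# A signal of disproportionate reporting requires at least three reports,
# ROR 95% CI lower bound > 1 and IC interval lower bound > 0. No
# multiple-testing adjustment is applied across events or PTs.

#' Construct a validated 2x2 contingency table
#'
#' @param a target drug and target event count
#' @param b target drug, other events
#' @param c other drugs, target event
#' @param d other drugs, other events
#' @return object of class `contingency_table`
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(is.finite(cells)), all(cells >= 0), sum(cells) > 0)
  structure(as.list(cells), N = sum(cells), class = "contingency_table")
}

#' Reporting odds ratio with 95% confidence interval
#'
#' ROR = ad/bc; the interval is exp(log ROR +/- 1.96 * sqrt(1/a + 1/b +
#' 1/c + 1/d)). When any cell is zero the Haldane-Anscombe correction
#' (add 0.5 to all four cells) is applied first; with the correction
#' disabled a degenerate table is flagged non-evaluable instead of
#' propagating NaN.
#'
#' @param t `contingency_table`
#' @param correct_zero apply the 0.5 correction on zero cells (default TRUE)
#' @return list `(ror, lower, upper, corrected, evaluable)`
#' @export
ror_estimate <- function(t, correct_zero = TRUE) {
  cells <- c(t$a, t$b, t$c, t$d)
  has_zero <- any(cells == 0)
  if (has_zero && !correct_zero) {
    return(list(ror = NA_real_, lower = NA_real_, upper = NA_real_,
                corrected = FALSE, evaluable = FALSE))
  }
  if (has_zero) cells <- cells + 0.5
  ror <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  list(ror = ror,
       lower = exp(log(ror) - 1.96 * se),
       upper = exp(log(ror) + 1.96 * se),
       corrected = has_zero, evaluable = TRUE)
}

#' Information component with 95% interval
#'
#' IC = log2((a + 0.5)/(E + 0.5)) with E = (a+b)(a+c)/N; the +0.5 terms
#' shrink small-count estimates towards zero. The default interval uses
#' the closed-form credibility approximation
#' lower = IC - 3.3 (a+0.5)^-1/2 - 2 (a+0.5)^-3/2,
#' upper = IC + 2.4 (a+0.5)^-1/2 - 0.5 (a+0.5)^-3/2;
#' `method = "gamma"` instead takes 2.5/97.5% quantiles of
#' log2 Gamma(a + 0.5, E + 0.5).
#'
#' @param t `contingency_table`
#' @param method `"approx"` (default) or `"gamma"`
#' @return list `(ic, lower, upper, expected)`
#' @export
ic_estimate <- function(t, method = c("approx", "gamma")) {
  method <- match.arg(method)
  a <- t$a; N <- attr(t, "N")
  E <- (t$a + t$b) * (t$a + t$c) / N
  ic <- log2((a + 0.5) / (E + 0.5))
  if (method == "approx") {
    lower <- ic - 3.3 * (a + 0.5)^-0.5 - 2 * (a + 0.5)^-1.5
    upper <- ic + 2.4 * (a + 0.5)^-0.5 - 0.5 * (a + 0.5)^-1.5
  } else {
    q <- stats::qgamma(c(0.025, 0.975), shape = a + 0.5, rate = E + 0.5)
    lower <- log2(q[[1L]]); upper <- log2(q[[2L]])
  }
  list(ic = ic, lower = lower, upper = upper, expected = E)
}

#' Full signal evaluation of one contingency table
#'
#' Combines [ror_estimate()] and [ic_estimate()] with the evaluation rule:
#' a pair is evaluated only with at least `min_reports` observed reports,
#' and flagged as a signal iff both the ROR CI lower bound exceeds 1 and
#' the IC interval lower bound exceeds 0.
#'
#' @param t `contingency_table`
#' @param min_reports evaluation threshold on the `a` cell (default 3)
#' @param ic_method passed to [ic_estimate()]
#' @return object of class `signal_estimate` (a one-row data.table with
#'   `n_obs`, `expected`, `ror`, `ror_lower`, `ror_upper`, `ic`,
#'   `ic_lower`, `ic_upper`, `evaluated`, `signal`)
#' @export
evaluate_signal <- function(t, min_reports = 3L, ic_method = "approx") {
  r <- ror_estimate(t)
  ic <- ic_estimate(t, method = ic_method)
  evaluated <- t$a >= min_reports && r$evaluable
  signal <- isTRUE(evaluated && r$lower > 1 && ic$lower > 0)
  out <- data.table::data.table(
    n_obs = t$a, expected = ic$expected,
    ror = r$ror, ror_lower = r$lower, ror_upper = r$upper,
    ic = ic$ic, ic_lower = ic$lower, ic_upper = ic$upper,
    evaluated = evaluated, signal = signal)
  class(out) <- c("signal_estimate", class(out))
  out
}

#' Label a deduplicated report universe for disproportionality analysis
#'
#' The universe is the comparison background: every deduplicated report
#' (optionally restricted to the same reporter qualifications as the drug
#' cohorts), with one drug label per report — the cohort drug when the
#' report belongs to exactly one cohort, `"other"` otherwise. A report
#' eligible for two cohorts is excluded and logged. Event labels come from
#' the dictionary.
#'
#' @param reports deduplicated `faers_reports`
#' @param dict `event_dictionary`
#' @param cohorts named list: drug label -> cohort rows from
#'   [select_cohort()]
#' @param reporter_filter reporter qualifications retained in the
#'   background, or NULL for all reports (default: health professionals,
#'   mirroring the cohorts' provenance)
#' @return object of class `pv_universe`: list with `tab` (primaryid,
#'   drug, fatal, sex, age_group, one logical column per event label),
#'   `reac` (primaryid, pt), `drugs`, `labels`, `excluded_overlap`
#' @export
label_universe <- function(reports, dict, cohorts,
                           reporter_filter = default_reporter_filter()) {
  stopifnot(inherits(reports, "faers_reports"))
  demo <- reports$demo
  if (!is.null(reporter_filter)) {
    demo <- demo[reporter_qualification %in% reporter_filter]
  }
  tab <- data.table::data.table(
    primaryid = demo$primaryid, drug = "other", fatal = demo$fatal,
    sex = demo$sex, age_group = age_group_of(demo$age_years))

  assign_n <- rep(0L, nrow(tab))
  for (dg in names(cohorts)) {
    i <- match(cohorts[[dg]]$primaryid, tab$primaryid)
    i <- i[!is.na(i)]
    data.table::set(tab, i = i, j = "drug", value = dg)
    assign_n[i] <- assign_n[i] + 1L
  }
  overlap <- tab$primaryid[assign_n > 1L]
  if (length(overlap)) tab <- tab[!primaryid %in% overlap]

  labels <- classify_reports(reports, dict)
  for (lab in dictionary_labels(dict)) {
    data.table::set(tab, j = lab,
                    value = tab$primaryid %in%
                      labels$primaryid[labels$label == lab])
  }
  structure(list(tab = tab,
                 reac = reports$reac[primaryid %in% tab$primaryid],
                 drugs = c(names(cohorts), "other"),
                 labels = dictionary_labels(dict),
                 excluded_overlap = overlap),
            class = "pv_universe")
}

#' @export
print.pv_universe <- function(x, ...) {
  cat(sprintf("<pv_universe> %d reports; drugs: %s\n", nrow(x$tab),
              paste(sprintf("%s=%d", x$drugs,
                            vapply(x$drugs, function(d) sum(x$tab$drug == d),
                                   integer(1))), collapse = " ")))
  invisible(x)
}

#' Build the drug-by-event contingency table against the full universe
#'
#' @param universe `pv_universe`
#' @param drug drug label present in the universe vocabulary
#' @param event event label (a dictionary label column)
#' @return `contingency_table`
#' @export
build_contingency <- function(universe, drug, event) {
  stopifnot(inherits(universe, "pv_universe"))
  if (!drug %in% universe$drugs) stop("unknown drug label: ", drug)
  if (!event %in% universe$labels) stop("unknown event label: ", event)
  has_drug <- universe$tab$drug == drug
  has_event <- universe$tab[[event]]
  contingency_table(sum(has_drug & has_event), sum(has_drug & !has_event),
                    sum(!has_drug & has_event), sum(!has_drug & !has_event))
}

#' Drug-by-event-category signal table against the full database
#'
#' One evaluated row per drug and event label: the Table-2-style output.
#'
#' @param universe `pv_universe`
#' @param drugs drug labels (default: all cohort drugs in the universe)
#' @param events event labels (default: all dictionary labels)
#' @param ... passed to [evaluate_signal()]
#' @return data.table with `drug`, `event` and the signal-estimate columns
#' @export
signal_table <- function(universe, drugs = setdiff(universe$drugs, "other"),
                         events = universe$labels, ...) {
  grid <- data.table::CJ(drug = drugs, event = events, sorted = FALSE)
  est <- lapply(seq_len(nrow(grid)), function(i) {
    evaluate_signal(build_contingency(universe, grid$drug[[i]],
                                      grid$event[[i]]), ...)
  })
  cbind(grid, data.table::rbindlist(est))
}

#' PT-level disproportionality scan for one drug
#'
#' Evaluates every Preferred Term in the vocabulary against the full
#' universe and reports the IC lower bound per PT (the forest-style scan).
#' PTs below the report threshold are retained in the audit list with
#' `evaluated = FALSE`; evaluated rows are sorted by IC lower bound,
#' descending.
#'
#' @param universe `pv_universe`
#' @param drug drug label
#' @param pt_vocabulary PTs to scan (default: every PT reported for the
#'   drug)
#' @param min_reports evaluation threshold (default 3)
#' @param ... passed to [evaluate_signal()]
#' @return data.table, one row per PT, with attribute `n_signals` = number
#'   of PTs with `signal = TRUE`
#' @export
pt_level_scan <- function(universe, drug, pt_vocabulary = NULL,
                          min_reports = 3L, ...) {
  stopifnot(inherits(universe, "pv_universe"))
  if (!drug %in% universe$drugs) stop("unknown drug label: ", drug)
  tab <- universe$tab
  drug_ids <- tab$primaryid[tab$drug == drug]
  n_drug <- length(drug_ids)
  n_tot <- nrow(tab)
  reac <- universe$reac
  if (is.null(pt_vocabulary)) {
    pt_vocabulary <- sort(unique(reac$pt[reac$primaryid %in% drug_ids]))
  }
  if (length(pt_vocabulary) == 0L) {
    out <- data.table::data.table(pt = character())
    data.table::setattr(out, "n_signals", 0L)
    return(out)
  }
  counts <- reac[pt %in% pt_vocabulary,
                 .(n_event = data.table::uniqueN(primaryid),
                   n_drug_event = data.table::uniqueN(
                     primaryid[primaryid %in% drug_ids])),
                 by = pt]
  counts <- merge(data.table::data.table(pt = pt_vocabulary), counts,
                  by = "pt", all.x = TRUE)
  counts[is.na(n_event), `:=`(n_event = 0L, n_drug_event = 0L)]
  est <- lapply(seq_len(nrow(counts)), function(i) {
    a <- counts$n_drug_event[[i]]
    ct <- contingency_table(a, n_drug - a, counts$n_event[[i]] - a,
                            n_tot - n_drug - counts$n_event[[i]] + a)
    evaluate_signal(ct, min_reports = min_reports, ...)
  })
  out <- cbind(counts[, .(pt)], data.table::rbindlist(est))
  data.table::setorder(out, -evaluated, -ic_lower)
  data.table::setattr(out, "n_signals", sum(out$signal))
  out[]
}

#' Head-to-head comparison of two drug cohorts
#'
#' Restricts the contingency table to the two cohorts: a/b from cohort A,
#' c/d from cohort B, with the same estimators and signal thresholds as
#' the full-database comparison. The cohorts must be disjoint (a report
#' primary-suspect for both drugs is excluded upstream and logged).
#'
#' @param cohortA,cohortB cohort rows from [select_cohort()]
#' @param event event label (a logical column of both cohort tables)
#' @param ... passed to [evaluate_signal()]
#' @return `signal_estimate` row
#' @export
head_to_head <- function(cohortA, cohortB, event, ...) {
  both <- intersect(cohortA$primaryid, cohortB$primaryid)
  if (length(both)) {
    stop("cohorts overlap on ", length(both),
         " report id(s); exclude dual-suspect reports upstream")
  }
  if (!event %in% names(cohortA) || !event %in% names(cohortB)) {
    stop("unknown event label: ", event)
  }
  a <- sum(cohortA[[event]]); c_ <- sum(cohortB[[event]])
  t <- contingency_table(a, nrow(cohortA) - a, c_, nrow(cohortB) - c_)
  evaluate_signal(t, ...)
}
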