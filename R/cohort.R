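# Cohort construction: the report-selection filters (drug of interest as
# primary suspect, intravenous route only, health-professional reporters,
# study window) and the descriptive summary of the selected reports.

#' Default synonym table for the three antiangiogenic mAbs
#'
#' Case-insensitive containment matching on verbatim drug name or active
#' ingredient. Intraocular-brand use (e.g. EYLEA aflibercept) is handled by
#' the route filter, not by name.
#'
#' @return named list: drug label -> character vector of synonyms
#' @export
default_drug_synonyms <- function() {
  list(
    bevacizumab = c("BEVACIZUMAB", "AVASTIN"),
    ramucirumab = c("RAMUCIRUMAB", "CYRAMZA"),
    aflibercept = c("AFLIBERCEPT", "ZALTRAP")
  )
}

#' Default health-professional reporter filter
#' @return character vector of reporter qualifications retained
#' @export
default_reporter_filter <- function() {
  c("physician", "pharmacist", "other_health_professional")
}

#' Default chemotherapy / other-antineoplastic ingredient lists
#'
#' Used by the treatment-strategy rule: any co-reported drug matching the
#' chemotherapy list puts the report in "plus_chemotherapy"; otherwise a
#' match in the non-chemo antineoplastic list gives "other_combined";
#' otherwise "monotherapy".
#'
#' @return named list with elements `chemotherapy` and `other_antineoplastic`
#' @export
default_therapy_lists <- function() {
  list(
    chemotherapy = c("OXALIPLATIN", "IRINOTECAN", "FLUOROURACIL",
                     "CAPECITABINE", "PACLITAXEL", "DOCETAXEL", "GEMCITABINE",
                     "CARBOPLATIN", "CISPLATIN", "PEMETREXED", "FOLFIRI",
                     "FOLFOX", "LEUCOVORIN", "TEMOZOLOMIDE"),
    other_antineoplastic = c("ERLOTINIB", "ATEZOLIZUMAB", "PEMBROLIZUMAB",
                             "NIVOLUMAB", "OLAPARIB", "INTERFERON")
  )
}

#' Default indication grouping patterns
#'
#' Containment patterns (upper-case) applied to indication PTs; first
#' matching group wins, otherwise "other"; reports with no informative
#' indication are "unknown".
#'
#' @return named list: group -> patterns
#' @export
default_indication_groups <- function() {
  list(
    colorectal = c("COLORECTAL", "COLON CANCER", "RECTAL CANCER", "COLON NEOPLASM"),
    nsclc = c("NON-SMALL CELL LUNG"),
    gastroesophageal = c("GASTRIC", "GASTROESOPHAGEAL", "OESOPHAGEAL",
                         "ESOPHAGEAL"),
    ovarian = c("OVARIAN"),
    glioblastoma = c("GLIOBLASTOMA", "GLIOMA")
  )
}

#' Build a cohort specification
#'
#' @param drug drug label declared in `synonyms`
#' @param synonyms named list: drug label -> synonym strings (default
#'   [default_drug_synonyms()])
#' @param required_role FAERS role code the drug entry must carry
#'   (default `"PS"`, primary suspect)
#' @param route_filter route classes retained (default intravenous only;
#'   unspecified routes are excluded unless listed explicitly)
#' @param reporter_filter reporter qualifications retained (default health
#'   professionals: physician, pharmacist, other health professional)
#' @param window `c(start, end)` quarter labels such as
#'   `c("2004Q1", "2024Q3")`, or NULL for no window filter
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(drug, synonyms = default_drug_synonyms(),
                        required_role = "PS",
                        route_filter = "intravenous",
                        reporter_filter = default_reporter_filter(),
                        window = NULL) {
  if (!drug %in% names(synonyms)) {
    stop("unknown drug '", drug, "': declare it with synonyms")
  }
  stopifnot(length(route_filter) >= 1L, length(reporter_filter) >= 1L)
  structure(list(drug = drug, synonyms = toupper(synonyms[[drug]]),
                 required_role = required_role,
                 route_filter = route_filter,
                 reporter_filter = reporter_filter,
                 window = window),
            class = "cohort_spec")
}

# Internal: containment match of any synonym in drugname or prod_ai.
match_drug_rows <- function(drug_dt, synonyms) {
  hay <- toupper(paste(drug_dt$drugname, drug_dt$prod_ai, sep = "\r"))
  hit <- rep(FALSE, nrow(drug_dt))
  for (s in synonyms) hit <- hit | grepl(s, hay, fixed = TRUE)
  hit
}

# Internal: age in years -> age group factor levels used throughout.
age_group_of <- function(age_years) {
  out <- rep("unknown", length(age_years))
  out[!is.na(age_years) & age_years < 18] <- "lt18"
  out[!is.na(age_years) & age_years >= 18 & age_years < 65] <- "18to64"
  out[!is.na(age_years) & age_years >= 65] <- "ge65"
  out
}

# Internal: quarter-window test on event dates; undated reports retained.
within_window <- function(event_pd, window) {
  if (is.null(window)) return(rep(TRUE, nrow(event_pd)))
  q <- partial_date_quarter(event_pd)
  yr_only <- event_pd$precision == "year"
  ok <- is.na(q) | (q >= window[[1L]] & q <= window[[2L]])
  ys <- as.integer(substr(window[[1L]], 1L, 4L))
  ye <- as.integer(substr(window[[2L]], 1L, 4L))
  ok[yr_only] <- event_pd$year[yr_only] >= ys & event_pd$year[yr_only] <= ye
  ok
}

#' Treatment-strategy classification for one report's co-medication
#'
#' @param co_names upper-case names/ingredients of co-reported drugs
#'   (roles SS/C/I)
#' @param therapy_lists as from [default_therapy_lists()]
#' @return `"plus_chemotherapy"`, `"other_combined"` or `"monotherapy"`
#' @export
therapy_class <- function(co_names, therapy_lists = default_therapy_lists()) {
  if (length(co_names) == 0L) return("monotherapy")
  hay <- toupper(paste(co_names, collapse = "\r"))
  if (any(vapply(therapy_lists$chemotherapy, grepl, logical(1), x = hay,
                 fixed = TRUE))) return("plus_chemotherapy")
  if (any(vapply(therapy_lists$other_antineoplastic, grepl, logical(1),
                 x = hay, fixed = TRUE))) return("other_combined")
  "monotherapy"
}

# Internal: indication group per primaryid from INDI rows.
indication_group_of <- function(indi, ids, groups = default_indication_groups()) {
  info <- indi[nzchar(indi_pt) &
                 !grepl("UNKNOWN INDICATION", indi_pt, fixed = TRUE)]
  res <- rep("unknown", length(ids))
  names(res) <- ids
  if (nrow(info)) {
    agg <- info[, .(txt = paste(indi_pt, collapse = "\r")), by = primaryid]
    agg <- agg[primaryid %in% ids]
    grp <- rep("other", nrow(agg))
    for (g in rev(names(groups))) {
      hit <- rep(FALSE, nrow(agg))
      for (p in groups[[g]]) hit <- hit | grepl(p, agg$txt, fixed = TRUE)
      grp[hit] <- g
    }
    res[agg$primaryid] <- grp
  }
  unname(res[as.character(ids)])
}

#' Select an analysis cohort
#'
#' Applies the four report-selection filters: (i) the drug of interest is
#' present with the required role code, (ii) that drug entry's route class
#' is in the route filter (unspecified routes excluded unless listed),
#' (iii) the reporter qualification is in the reporter filter, (iv) the
#' event date, when available, falls in the study window. Retained reports
#' are annotated with event-category labels, fatal flag, age group,
#' indication group, treatment strategy, and time to onset.
#'
#' @param reports deduplicated `faers_reports`
#' @param spec `cohort_spec`
#' @param dict `event_dictionary`
#' @param therapy_lists see [default_therapy_lists()]
#' @param indication_groups see [default_indication_groups()]
#' @return data.table of cohort rows: identifiers, demographics, one
#'   logical column per event label, `fatal`, `therapy_class`,
#'   `indication_group`, `onset_days` and `onset_excluded`
#' @export
select_cohort <- function(reports, spec, dict,
                          therapy_lists = default_therapy_lists(),
                          indication_groups = default_indication_groups()) {
  stopifnot(inherits(reports, "faers_reports"), inherits(spec, "cohort_spec"))
  drug <- reports$drug
  cand <- drug[match_drug_rows(drug, spec$synonyms) &
                 role_code == spec$required_role]
  cand <- cand[route_class %in% spec$route_filter]
  demo <- reports$demo[primaryid %in% unique(cand$primaryid)]
  demo <- demo[reporter_qualification %in% spec$reporter_filter]
  demo <- demo[within_window(parse_partial_date(event_dt), spec$window)]
  ids <- demo$primaryid
  cand <- cand[primaryid %in% ids]

  # onset from the primary-suspect entry's therapy rows; earliest start
  ther <- merge(reports$ther, unique(cand[, .(primaryid, drug_seq)]),
                by = c("primaryid", "drug_seq"))
  start_tok <- rep("", length(ids))
  if (nrow(ther)) {
    ther[, key := partial_date_key(start_dt)]
    earliest <- ther[nzchar(start_dt)][order(key), .SD[1L], by = primaryid]
    start_tok[match(earliest$primaryid, ids)] <- earliest$start_dt
  }
  ons <- onset_interval(demo$event_dt, start_tok)

  labels <- classify_reports(reports, dict)
  out <- data.table::data.table(
    primaryid = ids,
    drug = spec$drug,
    sex = demo$sex,
    age_years = demo$age_years,
    age_group = age_group_of(demo$age_years),
    fatal = demo$fatal,
    country = demo$country,
    indication_group = indication_group_of(reports$indi, ids,
                                           indication_groups),
    onset_days = ons$days,
    onset_excluded = ons$excluded
  )
  for (lab in dictionary_labels(dict)) {
    data.table::set(out, j = lab,
                    value = ids %in% labels$primaryid[labels$label == lab])
  }

  co <- reports$drug[primaryid %in% ids & role_code %in% c("SS", "C", "I")]
  co_txt <- co[, .(txt = list(toupper(paste(drugname, prod_ai)))),
               by = primaryid]
  tc <- rep("monotherapy", length(ids))
  if (nrow(co_txt)) {
    tc[match(co_txt$primaryid, ids)] <-
      vapply(co_txt$txt, therapy_class, character(1),
             therapy_lists = therapy_lists)
  }
  data.table::set(out, j = "therapy_class", value = tc)
  data.table::setorder(out, primaryid)
  out[]
}

#' Construct cohort rows with prescribed marginal counts
#'
#' Builds a synthetic cohort-row table whose per-block marginal counts are
#' exactly as given — the standard way to check descriptive-summary
#' arithmetic against a published characteristics table. Each marginal is
#' filled independently (the joint distribution is arbitrary). Onset bins
#' are populated with in-bin representative day values.
#'
#' @param drug drug label
#' @param n cohort size
#' @param sex_counts named counts over `F`/`M`/`unknown` (optional)
#' @param fatal_count number of fatal reports (optional)
#' @param indication_counts named counts over indication groups (optional;
#'   remainder becomes `"other"`)
#' @param onset_bin_counts named counts over the six onset bins (optional;
#'   rows beyond their total get `NA` onset)
#' @return data.table usable with [descriptive_summary()]
#' @export
cohort_rows_from_counts <- function(drug, n, sex_counts = NULL,
                                    fatal_count = NULL,
                                    indication_counts = NULL,
                                    onset_bin_counts = NULL) {
  fill <- function(counts, levels_default, rest) {
    if (is.null(counts)) return(rep(rest, n))
    stopifnot(sum(counts) <= n)
    c(rep(names(counts), counts), rep(rest, n - sum(counts)))
  }
  out <- data.table::data.table(
    primaryid = as.character(seq_len(n)),
    drug = drug,
    sex = fill(sex_counts, NULL, "unknown"),
    age_years = NA_real_,
    age_group = "unknown",
    fatal = seq_len(n) <= (fatal_count %||% 0L),
    country = "",
    indication_group = fill(indication_counts, NULL, "other"),
    therapy_class = "monotherapy")
  bin_rep <- c(`0-30d` = 15L, `31-60d` = 45L, `61-90d` = 75L,
               `91-180d` = 135L, `181-365d` = 270L, `>365d` = 400L)
  if (is.null(onset_bin_counts)) {
    out[, onset_days := NA_integer_]
  } else {
    stopifnot(sum(onset_bin_counts) <= n)
    days <- rep(bin_rep[names(onset_bin_counts)], onset_bin_counts)
    out[, onset_days := c(days, rep(NA_integer_, n - length(days)))]
  }
  out[, onset_excluded := ifelse(is.na(onset_days), "missing", NA_character_)]
  out[]
}

#' Descriptive summary of cohort rows
#'
#' Count/percentage blocks per drug matching the layout of a clinical
#' characteristics table: sex, age group, outcome, top countries, tumour
#' indication, treatment strategy, and time-to-onset bins with median and
#' IQR. Percentages use the full cohort as denominator except the onset
#' block, computed over reports with an evaluable onset (the available-n
#' convention). Percentages are rounded half-up to one decimal.
#'
#' @param rows cohort rows from [select_cohort()] (one or several drugs
#'   stacked)
#' @param top_countries how many countries to list (default 4)
#' @return data.table `(drug, block, level, n, denom, pct)`
#' @export
descriptive_summary <- function(rows, top_countries = 4L) {
  if (nrow(rows) == 0L) {
    return(data.table::data.table(drug = character(), block = character(),
                                  level = character(), n = numeric(),
                                  denom = numeric(), pct = numeric()))
  }
  pieces <- lapply(split(rows, rows$drug), function(r) {
    n_tot <- nrow(r)
    block <- function(name, level, n, denom = n_tot) {
      data.table::data.table(block = name, level = level, n = as.numeric(n),
                             denom = as.numeric(denom), pct = pct(n, denom))
    }
    count_block <- function(name, values, levels) {
      block(name, levels,
            vapply(levels, function(l) sum(values == l), numeric(1)))
    }
    out <- list(block("total", "reports", n_tot, n_tot))
    out$sex <- count_block("sex", r$sex, c("F", "M", "unknown"))
    out$age <- rbind(
      block("age", "available_n", sum(r$age_group != "unknown")),
      count_block("age", r$age_group, c("lt18", "18to64", "ge65", "unknown")))
    out$outcome <- block("outcome", c("fatal", "non_fatal"),
                         c(sum(r$fatal), sum(!r$fatal)))
    cn <- sort(table(r$country[nzchar(r$country)]), decreasing = TRUE)
    cn <- head(cn, top_countries)
    if (length(cn)) out$country <- block("country", names(cn), as.numeric(cn))
    out$indication <- count_block(
      "indication", r$indication_group,
      c("colorectal", "nsclc", "gastroesophageal", "ovarian", "glioblastoma",
        "other", "unknown"))
    out$therapy <- count_block(
      "therapy", r$therapy_class,
      c("plus_chemotherapy", "other_combined", "monotherapy"))

    days <- r$onset_days[!is.na(r$onset_days)]
    n_ons <- length(days)
    bins <- bin_onset(days)
    out$onset <- rbind(
      block("onset", "available_n", n_ons, n_ons),
      block("onset", ONSET_BIN_LABELS,
            vapply(ONSET_BIN_LABELS, function(b) sum(bins == b), numeric(1)),
            denom = n_ons))
    mi <- median_iqr(days)
    out$onset_stats <- data.table::data.table(
      block = "onset_stats", level = c("median", "q1", "q3"),
      n = c(mi$median, mi$q1, mi$q3), denom = n_ons, pct = NA_real_)
    dt <- data.table::rbindlist(out)
    dt[, drug := r$drug[1L]]
    dt
  })
  out <- data.table::rbindlist(pieces)
  data.table::setcolorder(out, c("drug", "block", "level", "n", "denom", "pct"))
  out[]
}
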