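# Synthetic FAERS archive generator. Emits quarterly DEMO/DRUG/REAC/OUTC/
# THER/INDI files in the modern `$`-delimited dialect with known ground
# truth: drug assignment, event sampling with planted odds multipliers on
# event probability given drug, exposure-dependent fatal outcome, per-drug
# log-normal onset times, then duplication, date truncation and
# missingness applied last. Because planted effects are odds multipliers,
# the implied true ROR of every planted signal is computable in closed
# form from the config, so parameter-recovery tests compare the estimator
# to exact expected cells rather than to the nominal multiplier.

#' Default simulation configuration
#'
#' The defaults emulate the study conditions of the antiangiogenic-mAb
#' thromboembolism analysis: three study drugs with report-volume weights
#' proportional to the published cohort sizes (92055 : 2814 : 2455)
#' against a dominant background, health-professional-majority reporters,
#' mostly intravenous routes with some intravitreal/missing routes,
#' baseline fatal probability 0.253 with exposure fatal-odds multiplier
#' 1.19, and per-drug log-normal onset with medians 60.5 / 26.5 / 31.5
#' days (dispersions back-computed from the published IQRs).
#'
#' @param seed mandatory integer seed (no silent nondeterminism)
#' @param n_reports number of cases before duplication (default 20000)
#' @return `sim_config` list; override any element before calling
#'   [generate_faers()]
#' @export
default_sim_config <- function(seed, n_reports = 20000L) {
  stopifnot(!missing(seed), is.finite(seed))
  dict <- load_event_dictionary(example_dictionary_path())
  tee_pts <- dictionary_pts(dict)
  pt_bg <- c(
    setNames(c(0.006, 0.005, 0.001, 0.001, 0.001), dict$categories$VTE),
    setNames(c(0.005, 0.002, 0.003, 0.003, 0.001, 0.001, 0.0005),
             dict$categories$ATE),
    setNames(c(0.004, 0.002, 0.001), dict$categories$unspecified_mixed),
    NAUSEA = 0.12, FATIGUE = 0.10, DIARRHOEA = 0.08, HEADACHE = 0.08,
    PYREXIA = 0.06, RASH = 0.06, VOMITING = 0.06, DIZZINESS = 0.05,
    ANAEMIA = 0.05, `DECREASED APPETITE` = 0.04)

  structure(list(
    seed = as.integer(seed),
    n_reports = as.integer(n_reports),
    quarters = c("2023Q1", "2023Q2", "2023Q3", "2023Q4"),
    dictionary = example_dictionary_path(),
    drug_catalog = data.table::data.table(
      drug = c("bevacizumab", "ramucirumab", "aflibercept", "background"),
      ingredient = c("BEVACIZUMAB", "RAMUCIRUMAB", "AFLIBERCEPT", ""),
      brand = c("AVASTIN", "CYRAMZA", "ZALTRAP", ""),
      weight = c(0.189 * c(92055, 2814, 2455) / 92055, 0.8),
      p_iv = c(0.90, 0.97, 0.90, 0.70),
      p_intraocular = c(0.05, 0.0, 0.05, 0.0),
      p_route_missing = c(0.04, 0.02, 0.04, 0.25),
      onset_median = c(60.5, 26.5, 31.5, 45),
      onset_sigma = c(1.47, 1.27, 1.91, 1.40),
      p_chemo_co = c(0.63, 0.57, 0.75, 0.20)),
    pt_catalog = pt_bg,
    tee_pts = tee_pts,
    planted_signals = list(
      list(drug = "bevacizumab", event = "VTE", multiplier = 2.5),
      list(drug = "bevacizumab", event = "ATE", multiplier = 1.35),
      list(drug = "bevacizumab", event = "unspecified_mixed", multiplier = 1.8),
      list(drug = "ramucirumab", event = "VTE", multiplier = 2.3),
      list(drug = "ramucirumab", event = "ATE", multiplier = 1.7),
      list(drug = "ramucirumab", event = "unspecified_mixed", multiplier = 1.6),
      list(drug = "aflibercept", event = "VTE", multiplier = 2.2),
      list(drug = "aflibercept", event = "ATE", multiplier = 2.2),
      list(drug = "aflibercept", event = "unspecified_mixed", multiplier = 2.5)),
    fatality = list(baseline = 0.253, exposure_or = 1.19, age_ge65_or = 1.3),
    demographics = list(
      sex = c(F = 0.43, M = 0.42, unknown = 0.15),
      age_group = c(lt18 = 0.02, `18to64` = 0.42, ge65 = 0.36, unknown = 0.20),
      country = c(US = 0.30, JP = 0.21, DE = 0.07, FR = 0.07, GB = 0.05,
                  OTHER = 0.30)),
    reporter = c(MD = 0.55, PH = 0.15, OT = 0.12, RN = 0.03, CN = 0.13,
                 LW = 0.02),
    indications = list(
      # "NONE" is a sentinel for a missing indication row
      bevacizumab = c(`COLORECTAL CANCER` = 0.35,
                      `NON-SMALL CELL LUNG CANCER` = 0.08,
                      `OVARIAN CANCER` = 0.08, GLIOBLASTOMA = 0.07,
                      `BREAST CANCER` = 0.20, `GASTRIC CANCER` = 0.02,
                      NONE = 0.05, `CERVIX CANCER` = 0.15),
      ramucirumab = c(`GASTRIC CANCER` = 0.44, `COLORECTAL CANCER` = 0.12,
                      `NON-SMALL CELL LUNG CANCER` = 0.11,
                      `HEPATIC CANCER` = 0.20, NONE = 0.13),
      aflibercept = c(`COLORECTAL CANCER` = 0.78, `GASTRIC CANCER` = 0.04,
                      NONE = 0.15, `BREAST CANCER` = 0.03),
      background = c(HYPERTENSION = 0.2, `DIABETES MELLITUS` = 0.2,
                     `BREAST CANCER` = 0.1, NONE = 0.5)),
    duplicate_rate = 0.0,
    partial_date_rate = 0.0,
    missingness = list(age = 0.20, event_dt = 0.15, start_dt = 0.25,
                       sex = 0.0),
    reporting_delay = c(3L, 60L)
  ), class = "sim_config")
}

# Internal: validate a sim_config.
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config") || is.list(config))
  stopifnot(is.finite(config$seed), config$n_reports > 0)
  probs <- c(config$pt_catalog, unlist(config$missingness),
             config$duplicate_rate, config$partial_date_rate)
  stopifnot(all(probs >= 0 & probs <= 1))
  for (s in config$planted_signals) {
    stopifnot(s$multiplier > 0)
    if (!s$drug %in% config$drug_catalog$drug) {
      stop("planted signal references unknown drug: ", s$drug)
    }
    dict <- load_event_dictionary(config$dictionary)
    known <- c(names(dict$categories), names(dict$subtypes),
               names(config$pt_catalog))
    if (!s$event %in% known) {
      stop("planted signal references unknown PT/category: ", s$event)
    }
  }
  invisible(config)
}

# Internal: planted odds-multiplier matrix, drugs x PTs.
signal_multipliers <- function(config) {
  dict <- load_event_dictionary(config$dictionary)
  pts <- names(config$pt_catalog)
  drugs <- config$drug_catalog$drug
  M <- matrix(1, nrow = length(drugs), ncol = length(pts),
              dimnames = list(drugs, pts))
  for (s in config$planted_signals) {
    target <- if (s$event %in% c(names(dict$categories), names(dict$subtypes))) {
      dictionary_pts(dict, s$event)
    } else s$event
    target <- intersect(target, pts)
    M[s$drug, target] <- M[s$drug, target] * s$multiplier
  }
  M
}

#' Closed-form expected truth for every drug-by-label pair
#'
#' Computes, from the configuration alone, the per-drug probability of
#' each event label (one minus the product of per-PT miss probabilities),
#' the expected contingency cells at `n_reports`, and the implied true
#' reporting odds ratio against all other drugs. This is the reference the
#' recovery tests compare estimates to.
#'
#' @param config `sim_config`
#' @return data.table `(drug, label, p_event, exp_a, exp_b, exp_c, exp_d,
#'   true_ror)`
#' @export
planted_truth <- function(config) {
  dict <- load_event_dictionary(config$dictionary)
  M <- signal_multipliers(config)
  p0 <- config$pt_catalog
  w <- config$drug_catalog$weight / sum(config$drug_catalog$weight)
  drugs <- config$drug_catalog$drug
  labels <- dictionary_labels(dict)
  p_evt <- function(drug, label) {
    pts <- intersect(dictionary_pts(dict, label), names(p0))
    pj <- plogis(stats::qlogis(p0[pts]) + log(M[drug, pts]))
    1 - prod(1 - pj)
  }
  out <- data.table::CJ(drug = drugs, label = labels, sorted = FALSE)
  out[, p_event := mapply(p_evt, drug, label)]
  n <- config$n_reports
  out[, `:=`(
    exp_a = n * w[match(drug, drugs)] * p_event,
    exp_b = n * w[match(drug, drugs)] * (1 - p_event))]
  pc <- vapply(seq_len(nrow(out)), function(i) {
    others <- setdiff(drugs, out$drug[[i]])
    sum(w[match(others, drugs)] *
          vapply(others, p_evt, numeric(1), label = out$label[[i]]))
  }, numeric(1))
  w_other <- 1 - w[match(out$drug, drugs)]
  out[, `:=`(exp_c = n * pc, exp_d = n * (w_other - pc))]
  out[, true_ror := (exp_a * exp_d) / (exp_b * exp_c)]
  out[]
}

# Internal: sample categorical by named probability vector.
sample_cat <- function(n, probs) {
  i <- pmin(findInterval(runif(n), cumsum(probs) / sum(probs)) + 1L,
            length(probs))
  names(probs)[i]
}

# Internal: random Date within a quarter label (vectorised).
random_date_in_quarter <- function(qlab) {
  yr <- as.integer(substr(qlab, 1, 4))
  q <- as.integer(substr(qlab, 6, 6))
  start <- as.Date(sprintf("%d-%02d-01", yr, (q - 1L) * 3L + 1L))
  uq <- !duplicated(qlab)
  ulen <- vapply(which(uq), function(i) {
    as.integer(seq(start[[i]], by = "3 months", length.out = 2)[[2L]] -
                 start[[i]])
  }, integer(1))
  len <- ulen[match(qlab, qlab[uq])]
  start + floor(runif(length(qlab)) * len)
}

fmt_dt <- function(dates) format(dates, "%Y%m%d")

#' Generate a synthetic FAERS archive with ground truth
#'
#' Report-level sampling: drug assignment, per-PT event sampling with the
#' planted odds multipliers, fatal-outcome sampling with
#' exposure-dependent odds, onset from the drug's log-normal, then
#' duplication (later-quarter versions with advanced FDA_DT), date
#' truncation, and missingness. Identical (config, seed) pairs yield
#' byte-identical archives.
#'
#' @param config `sim_config` from [default_sim_config()] (possibly
#'   modified)
#' @param out_dir output directory; per-quarter subdirectories with
#'   DEMO/DRUG/REAC/OUTC/THER/INDI files are written, plus
#'   `truth_cases.tsv` and `truth_summary.json`
#' @return invisibly, list `(dir, cases, truth, config)` where `cases` is
#'   the per-case ground-truth data.table
#' @export
generate_faers <- function(config, out_dir) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_reports
  cat_ <- config$drug_catalog
  dict <- load_event_dictionary(config$dictionary)

  drug_idx <- pmin(findInterval(runif(n), cumsum(cat_$weight) /
                                  sum(cat_$weight)) + 1L, nrow(cat_))
  drug <- cat_$drug[drug_idx]

  # events: per-PT Bernoulli with planted odds multipliers
  M <- signal_multipliers(config)
  p0 <- config$pt_catalog
  J <- length(p0)
  P <- plogis(matrix(stats::qlogis(p0), n, J, byrow = TRUE) +
                log(M)[drug_idx, , drop = FALSE])
  has_pt <- matrix(runif(n * J), n, J) < P
  colnames(has_pt) <- names(p0)
  none <- rowSums(has_pt) == 0L
  has_pt[none, "NAUSEA"] <- TRUE
  exposure <- rowSums(has_pt[, config$tee_pts, drop = FALSE]) > 0L

  # demographics
  dem <- config$demographics
  age_grp <- sample_cat(n, dem$age_group)
  age <- round(ifelse(age_grp == "lt18", 1 + runif(n) * 16,
                      ifelse(age_grp == "18to64", 18 + runif(n) * 46,
                             ifelse(age_grp == "ge65", 65 + runif(n) * 25,
                                    NA_real_))))
  sex <- sample_cat(n, dem$sex)
  sex[sex == "unknown"] <- ""
  country <- sample_cat(n, dem$country)
  reporter <- sample_cat(n, config$reporter)

  # fatal outcome with exposure-dependent odds
  fat <- config$fatality
  eta <- stats::qlogis(fat$baseline) + log(fat$exposure_or) * exposure +
    log(fat$age_ge65_or) * (!is.na(age) & age >= 65)
  fatal <- runif(n) < plogis(eta)

  # onset and dates
  med <- cat_$onset_median[drug_idx]
  sig <- cat_$onset_sigma[drug_idx]
  onset <- pmax(0L, as.integer(round(rlnorm(n, log(med), sig))))
  quarter <- sample(config$quarters, n, replace = TRUE)
  start_date <- random_date_in_quarter(quarter)
  event_date <- start_date + onset
  delay <- config$reporting_delay
  fda_date <- event_date + delay[[1L]] +
    floor(runif(n) * (delay[[2L]] - delay[[1L]] + 1L))

  # routes and co-medication
  u <- runif(n)
  p_iv <- cat_$p_iv[drug_idx]; p_io <- cat_$p_intraocular[drug_idx]
  p_m <- cat_$p_route_missing[drug_idx]
  route <- ifelse(u < p_iv, "INTRAVENOUS",
                  ifelse(u < p_iv + p_io, "INTRAVITREAL",
                         ifelse(u < p_iv + p_io + p_m, "", "ORAL")))
  chemo_pool <- default_therapy_lists()$chemotherapy
  has_chemo <- runif(n) < cat_$p_chemo_co[drug_idx]
  chemo_name <- sample(chemo_pool, n, replace = TRUE)

  indication <- character(n)
  for (dg in names(config$indications)) {
    i <- drug == dg
    if (any(i)) indication[i] <- sample_cat(sum(i), config$indications[[dg]])
  }
  indication[indication == "NONE"] <- ""

  bg_names <- sprintf("INGREDIENT_%02d", seq_len(20))
  verbatim <- ifelse(drug == "background",
                     bg_names[1L + (seq_len(n) %% 20L)],
                     cat_$brand[drug_idx])
  prod_ai <- ifelse(drug == "background",
                    bg_names[1L + (seq_len(n) %% 20L)],
                    cat_$ingredient[drug_idx])

  caseid <- as.character(seq_len(n) + 10000000L)
  cases <- data.table::data.table(
    caseid = caseid, drug = drug, exposure = exposure, fatal = fatal,
    onset_true = onset, sex = ifelse(nzchar(sex), sex, "unknown"),
    age_true = age, reporter = reporter, route = route,
    quarter = quarter, indication = indication,
    eligible = drug != "background" & route == "INTRAVENOUS" &
      reporter %in% c("MD", "PH", "OT"))

  # missingness and truncation applied last
  miss <- config$missingness
  age_tok <- ifelse(is.na(age) | runif(n) < miss$age, "",
                    as.character(age))
  trunc_tok <- function(tok, rate) {
    r <- runif(length(tok))
    tok[r < rate / 2] <- substr(tok[r < rate / 2], 1, 6)      # to month
    i <- r >= rate / 2 & r < rate
    tok[i] <- substr(tok[i], 1, 4)                            # to year
    tok
  }
  event_tok <- fmt_dt(event_date)
  event_tok[runif(n) < miss$event_dt] <- ""
  event_tok <- trunc_tok(event_tok, config$partial_date_rate)
  start_tok <- fmt_dt(start_date)
  start_tok[runif(n) < miss$start_dt] <- ""
  start_tok <- trunc_tok(start_tok, config$partial_date_rate)

  # duplication: later-quarter second versions with advanced FDA_DT
  dup <- runif(n) < config$duplicate_rate
  cases[, n_versions := 1L + as.integer(dup)]

  build_version <- function(version, idx) {
    data.table::data.table(
      i = idx, version = version,
      primaryid = paste0(caseid[idx], version),
      caseid = caseid[idx],
      fda_dt = fmt_dt(fda_date[idx] + (version - 1L) * 95L),
      quarter = if (version == 1L) quarter[idx] else
        vapply(quarter[idx], function(q) {
          pos <- match(q, config$quarters)
          config$quarters[[min(pos + 1L, length(config$quarters))]]
        }, character(1)))
  }
  versions <- rbind(build_version(1L, seq_len(n)),
                    if (any(dup)) build_version(2L, which(dup)))

  demo <- versions[, .(
    PRIMARYID = primaryid, CASEID = caseid, CASEVERSION = version,
    FDA_DT = fda_dt, EVENT_DT = event_tok[i], AGE = age_tok[i],
    AGE_COD = ifelse(nzchar(age_tok[i]), "YR", ""), SEX = sex[i],
    OCCP_COD = reporter[i], REPORTER_COUNTRY = country[i], quarter)]

  drug_rows <- versions[, .(
    PRIMARYID = primaryid, CASEID = caseid, DRUG_SEQ = "1", ROLE_COD = "PS",
    DRUGNAME = verbatim[i], PROD_AI = prod_ai[i], ROUTE = route[i], quarter)]
  co <- versions[has_chemo[i]]
  if (nrow(co)) {
    drug_rows <- rbind(drug_rows, co[, .(
      PRIMARYID = primaryid, CASEID = caseid, DRUG_SEQ = "2",
      ROLE_COD = "SS", DRUGNAME = chemo_name[i], PROD_AI = chemo_name[i],
      ROUTE = "INTRAVENOUS", quarter)])
  }

  pt_idx <- which(has_pt, arr.ind = TRUE)
  pt_long <- data.table::data.table(i = pt_idx[, 1L],
                                    pt = names(p0)[pt_idx[, 2L]])
  reac_rows <- merge(versions, pt_long, by = "i", allow.cartesian = TRUE)[
    , .(PRIMARYID = primaryid, CASEID = caseid, PT = pt, quarter)]

  outc_rows <- versions[fatal[i]][, .(
    PRIMARYID = primaryid, CASEID = caseid, OUTC_COD = "DE", quarter)]
  hosp <- versions[!fatal[i] & runif(nrow(versions)) < 0.3]
  if (nrow(hosp)) {
    outc_rows <- rbind(outc_rows, hosp[, .(
      PRIMARYID = primaryid, CASEID = caseid, OUTC_COD = "HO", quarter)])
  }

  ther_rows <- versions[, .(
    PRIMARYID = primaryid, CASEID = caseid, DSG_DRUG_SEQ = "1",
    START_DT = start_tok[i], END_DT = "", quarter)]
  indi_rows <- versions[nzchar(indication[i])][, .(
    PRIMARYID = primaryid, CASEID = caseid, INDI_DRUG_SEQ = "1",
    INDI_PT = indication[i], quarter)]

  # write per-quarter files
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list(DEMO = demo, DRUG = drug_rows, REAC = reac_rows,
               OUTC = outc_rows, THER = ther_rows, INDI = indi_rows)
  for (q in config$quarters) {
    qdir <- file.path(out_dir, q)
    dir.create(qdir, showWarnings = FALSE)
    qq <- paste0(substr(q, 3, 4), "Q", substr(q, 6, 6))
    for (tb in names(tabs)) {
      sub <- tabs[[tb]][quarter == q][, quarter := NULL]
      data.table::setorder(sub, PRIMARYID)
      f <- file.path(qdir, sprintf("%s%s.txt", tb, qq))
      data.table::fwrite(sub, f, sep = "$", quote = FALSE)
    }
  }
  data.table::fwrite(cases, file.path(out_dir, "truth_cases.tsv"), sep = "\t")
  truth <- planted_truth(config)
  jsonlite::write_json(
    list(seed = config$seed, n_reports = config$n_reports,
         n_cases = nrow(cases), n_rows_emitted = nrow(versions),
         planted = truth),
    file.path(out_dir, "truth_summary.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(dir = out_dir, cases = cases, truth = truth,
                 config = config))
}

#' Verify pipeline outputs against generator ground truth
#'
#' Checks that deduplication recovered exactly the true case set, that the
#' cohort filters retained exactly the truly eligible reports, and that
#' estimated RORs for the planted signals fall inside their own 95%
#' confidence intervals' span around the theoretical values.
#'
#' @param reports deduplicated `faers_reports` from the generated archive
#' @param cohorts named list of cohort rows per study drug
#' @param universe `pv_universe` built from the same reports
#' @param gen result of [generate_faers()]
#' @return data.table `(check, pass, detail)`
#' @export
verify_against_truth <- function(reports, cohorts, universe, gen) {
  res <- list()
  add <- function(check, pass, detail) {
    res[[length(res) + 1L]] <<- data.table::data.table(
      check = check, pass = pass, detail = detail)
  }
  truth_cases <- gen$cases
  add("dedup_case_count", nrow(reports$demo) == nrow(truth_cases),
      sprintf("%d vs %d", nrow(reports$demo), nrow(truth_cases)))
  add("dedup_case_ids",
      setequal(reports$demo$caseid, truth_cases$caseid), "case id sets")
  surv_version_ok <- all(
    substr(reports$demo$primaryid, nchar(reports$demo$primaryid),
           nchar(reports$demo$primaryid)) ==
      as.character(truth_cases$n_versions[
        match(reports$demo$caseid, truth_cases$caseid)]))
  add("dedup_latest_version", surv_version_ok,
      "survivor is the latest emitted version")

  for (dg in names(cohorts)) {
    want <- truth_cases[eligible == TRUE & drug == dg, caseid]
    got <- reports$demo$caseid[match(cohorts[[dg]]$primaryid,
                                     reports$demo$primaryid)]
    add(paste0("cohort_exact_", dg), setequal(want, got),
        sprintf("%d vs %d reports", length(got), length(want)))
  }

  truth <- gen$truth
  for (i in which(truth$drug != "background" & truth$label == "VTE")) {
    dg <- truth$drug[[i]]
    est <- evaluate_signal(build_contingency(universe, dg, "VTE"))
    span <- log(est$ror_upper) - log(est$ror)
    ok <- is.finite(est$ror) &&
      abs(log(est$ror) - log(truth$true_ror[[i]])) < span
    add(paste0("ror_recovery_", dg, "_VTE"), ok,
        sprintf("est %.3f vs true %.3f", est$ror, truth$true_ror[[i]]))
  }
  data.table::rbindlist(res)
}
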