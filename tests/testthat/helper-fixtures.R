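# Shared fixture builders. Everything is generated in code: tiny ASCII
# archives assembled from literal lines, and a minimal event dictionary.

ascii_lines <- function(header, ...) c(header, ...)

# A small modern-dialect archive: 4 cases, one duplicated (case 555 has
# two versions), one consumer-reported, one intravitreal.
tiny_archive_sets <- function() {
  demo <- parse_ascii_table(c(
    "PRIMARYID$CASEID$FDA_DT$EVENT_DT$AGE$AGE_COD$SEX$OCCP_COD$REPORTER_COUNTRY",
    "5551$555$20190101$20181201$72$YR$F$MD$US",
    "5552$555$20200101$20181201$72$YR$F$MD$US",
    "6661$666$20190601$20190520$6$MON$M$CN$JP",
    "7771$777$20190701$201905$65$YR$M$PH$FR",
    "8881$888$20190801$20190710$54$YR$F$OT$DE"),
    "DEMO", "modern")
  drug <- parse_ascii_table(c(
    "PRIMARYID$CASEID$DRUG_SEQ$ROLE_COD$DRUGNAME$PROD_AI$ROUTE",
    "5551$555$1$PS$AVASTIN$BEVACIZUMAB$INTRAVENOUS",
    "5552$555$1$PS$AVASTIN$BEVACIZUMAB$INTRAVENOUS",
    "5552$555$2$SS$OXALIPLATIN$OXALIPLATIN$INTRAVENOUS",
    "6661$666$1$PS$AVASTIN$BEVACIZUMAB$INTRAVENOUS",
    "7771$777$1$PS$CYRAMZA$RAMUCIRUMAB$INTRAVENOUS DRIP",
    "8881$888$1$PS$EYLEA$AFLIBERCEPT$INTRAVITREAL"),
    "DRUG", "modern")
  reac <- parse_ascii_table(c(
    "PRIMARYID$CASEID$PT",
    "5551$555$Pulmonary embolism",
    "5552$555$Pulmonary embolism",
    "6661$666$Nausea",
    "7771$777$Deep vein thrombosis",
    "8881$888$Myocardial infarction"),
    "REAC", "modern")
  outc <- parse_ascii_table(c(
    "PRIMARYID$CASEID$OUTC_COD",
    "5552$555$DE",
    "7771$777$HO"),
    "OUTC", "modern")
  ther <- parse_ascii_table(c(
    "PRIMARYID$CASEID$DSG_DRUG_SEQ$START_DT",
    "5552$555$1$20181001",
    "7771$777$1$20190301",
    "8881$888$1$20190601"),
    "THER", "modern")
  indi <- parse_ascii_table(c(
    "PRIMARYID$CASEID$INDI_DRUG_SEQ$INDI_PT",
    "5552$555$1$COLORECTAL CANCER",
    "7771$777$1$GASTRIC CANCER"),
    "INDI", "modern")
  list(demo, drug, reac, outc, ther, indi)
}

tiny_reports <- function() deduplicate(assemble_reports(tiny_archive_sets()))

test_dict <- function() load_event_dictionary(example_dictionary_path())

# Hand-built labelled universe: counts chosen so the contingency cells are
# easy to derive by brute-force set counting in the tests. `n_event` is
# the total number of event reports, of which `n_drug_event` carry the drug.
toy_universe <- function(n = 100, n_drug = 10, n_drug_event = 4,
                         n_event = 20) {
  ids <- as.character(seq_len(n))
  n_oth_evt <- n_event - n_drug_event
  tab <- data.table::data.table(
    primaryid = ids,
    drug = c(rep("drugX", n_drug), rep("other", n - n_drug)),
    fatal = FALSE, sex = "M", age_group = "18to64",
    evt = c(rep(TRUE, n_drug_event), rep(FALSE, n_drug - n_drug_event),
            rep(TRUE, n_oth_evt), rep(FALSE, n - n_drug - n_oth_evt)))
  structure(list(tab = tab,
                 reac = data.table::data.table(
                   primaryid = tab$primaryid[tab$evt], pt = "EVT_PT"),
                 drugs = c("drugX", "other"), labels = "evt",
                 excluded_overlap = character()),
            class = "pv_universe")
}

# Minimal cohort-row table for model tests: exposure/outcome with
# covariates sampled under a known logistic model.
simulate_model_rows <- function(n, beta_exposure, seed,
                                p_exposure = 0.3, baseline = 0.25) {
  set.seed(seed)
  exposure <- runif(n) < p_exposure
  sex <- sample(c("M", "F"), n, replace = TRUE)
  age <- sample(c("18to64", "ge65"), n, replace = TRUE)
  drug <- sample(c("bevacizumab", "ramucirumab"), n, replace = TRUE,
                 prob = c(0.8, 0.2))
  eta <- qlogis(baseline) + beta_exposure * exposure + 0.2 * (sex == "F") +
    0.3 * (age == "ge65") - 0.1 * (drug == "ramucirumab")
  data.table::data.table(
    primaryid = as.character(seq_len(n)), drug = drug, sex = sex,
    age_group = age, fatal = runif(n) < plogis(eta), overall_TEE = exposure,
    indication_group = "other")
}
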