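test_that("cohort selection applies role, route, reporter and window filters", {
  rep <- tiny_reports()
  d <- test_dict()
  bev <- select_cohort(rep, cohort_spec("bevacizumab"), d)
  # case 555 (MD, IV, PS) passes; 666 is consumer-reported
  expect_equal(bev$primaryid, "5552")
  expect_true(bev$PE)
  expect_true(bev$overall_TEE)
  expect_true(bev$fatal)
  expect_equal(bev$therapy_class, "plus_chemotherapy")
  expect_equal(bev$indication_group, "colorectal")
  expect_equal(bev$onset_days, 61L)  # 2018-10-01 to 2018-12-01

  # intravitreal aflibercept excluded under the intravenous route filter
  afl <- select_cohort(rep, cohort_spec("aflibercept"), d)
  expect_equal(nrow(afl), 0L)
  # but retained when the route filter admits intraocular use
  afl2 <- select_cohort(rep, cohort_spec("aflibercept",
                                         route_filter = "intraocular"), d)
  expect_equal(afl2$primaryid, "8881")

  ram <- select_cohort(rep, cohort_spec("ramucirumab"), d)
  expect_equal(ram$primaryid, "7771")  # "INTRAVENOUS DRIP" counts as IV
  expect_equal(ram$onset_excluded, "partial_precision")

  # window excludes the 2018 event
  bev_w <- select_cohort(rep, cohort_spec("bevacizumab",
                                          window = c("2019Q1", "2019Q4")), d)
  expect_equal(nrow(bev_w), 0L)

  expect_error(cohort_spec("unheard-of-drug"), "unknown drug")
})

test_that("the selection filters commute with manual filtering in any order", {
  gen <- generate_faers(default_sim_config(seed = 303, n_reports = 800L),
                        file.path(tempdir(), "commute"))
  rep <- deduplicate(assemble_reports(read_faers_archive(gen$dir)))
  d <- test_dict()
  got <- select_cohort(rep, cohort_spec("bevacizumab"), d)$primaryid

  # independent filtering applied in a different order: reporter first,
  # then role+name, then route
  demo_ok <- rep$demo[reporter_qualification %in%
                        default_reporter_filter(), primaryid]
  dr <- rep$drug[primaryid %in% demo_ok]
  dr <- dr[role_code == "PS" &
             (grepl("BEVACIZUMAB", paste(drugname, prod_ai)) |
                grepl("AVASTIN", paste(drugname, prod_ai)))]
  manual <- sort(unique(dr[route_class == "intravenous", primaryid]))
  expect_equal(sort(got), manual)
})

test_that("treatment strategy follows the configured ingredient lists", {
  expect_equal(therapy_class("OXALIPLATIN"), "plus_chemotherapy")
  expect_equal(therapy_class(character()), "monotherapy")
  expect_equal(therapy_class("ERLOTINIB"), "other_combined")
  # co-drug in neither list falls back to monotherapy
  expect_equal(therapy_class("OMEPRAZOLE"), "monotherapy")
  # chemotherapy takes precedence over other antineoplastics
  expect_equal(therapy_class(c("ERLOTINIB", "OXALIPLATIN")),
               "plus_chemotherapy")
})

test_that("descriptive summary blocks are internally consistent", {
  rows <- cohort_rows_from_counts(
    "drugA", 40, sex_counts = c(M = 40), fatal_count = 10,
    onset_bin_counts = c(`0-30d` = 10, `31-60d` = 5))
  s <- descriptive_summary(rows)
  expect_equal(s[block == "sex" & level == "M", pct], 100)
  expect_equal(s[block == "sex" & level == "F", pct], 0)
  expect_equal(s[block == "outcome" & level == "fatal", pct], 25)
  # onset percentages run over the available-n subset
  expect_equal(s[block == "onset" & level == "available_n", n], 15)
  expect_equal(s[block == "onset" & level == "0-30d", pct],
               round_half_up(100 * 10 / 15))
  # percentage cells sum to 100 within a shared-denominator block
  for (b in c("sex", "outcome", "indication", "therapy")) {
    expect_lt(abs(sum(s[block == b, pct]) - 100), 0.11)
  }
  expect_lt(abs(sum(s[block == "onset" & level != "available_n", pct]) - 100),
            0.11)
  # sex/outcome counts add up to the cohort size
  expect_equal(sum(s[block == "sex", n]), 40)
  expect_equal(sum(s[block == "outcome", n]), 40)
})

test_that("empty cohorts summarise to an empty table rather than dividing by zero", {
  empty <- cohort_rows_from_counts("drugA", 1)[0]
  expect_equal(nrow(descriptive_summary(empty)), 0L)
})

test_that("age groups are consistent with age in years", {
  rep <- tiny_reports()
  d <- test_dict()
  rows <- rbind(select_cohort(rep, cohort_spec("bevacizumab"), d),
                select_cohort(rep, cohort_spec("ramucirumab"), d))
  ag <- rows$age_group
  ay <- rows$age_years
  expect_true(all(ag[!is.na(ay) & ay < 18] == "lt18"))
  expect_true(all(ag[!is.na(ay) & ay >= 18 & ay < 65] == "18to64"))
  expect_true(all(ag[!is.na(ay) & ay >= 65] == "ge65"))
  expect_true(all(ag[is.na(ay)] == "unknown"))
})
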