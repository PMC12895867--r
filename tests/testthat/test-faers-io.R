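test_that("dollar-delimited tables parse row-identically and log malformed lines", {
  t1 <- parse_ascii_table(c("PRIMARYID$CASEID$EVENT_DT", "1001$555$20190301"),
                          "DEMO", "modern")
  expect_equal(nrow(t1$rows), 1L)
  expect_equal(as.list(t1$rows),
               list(PRIMARYID = "1001", CASEID = "555",
                    EVENT_DT = "20190301"))

  t2 <- parse_ascii_table("PRIMARYID$CASEID$EVENT_DT", "DEMO", "modern")
  expect_equal(nrow(t2$rows), 0L)

  t3 <- parse_ascii_table(c("PRIMARYID$CASEID$EVENT_DT",
                            "1001$555$20190301",
                            "1002$556",
                            "1003$557$20190501"),
                          "DEMO", "modern")
  expect_equal(nrow(t3$rows), 2L)
  expect_equal(nrow(t3$rejects), 1L)
  expect_equal(t3$rejects$reason, "field_count_mismatch")

  expect_error(parse_ascii_table("CASEID$EVENT_DT", "DEMO", "modern"),
               "PRIMARYID")
  expect_error(parse_ascii_table("PRIMARYID$PT", "REAC", "legacy"), "ISR")
})

test_that("empty fields survive parsing as empty strings", {
  t <- parse_ascii_table(c("PRIMARYID$AGE$SEX", "1$72$", "2$$F"),
                         "DEMO", "modern")
  expect_equal(t$rows$SEX, c("", "F"))
  expect_equal(t$rows$AGE, c("72", ""))
})

test_that("assembly converts ages, decodes reporters, and keeps child rows once", {
  rep <- assemble_reports(tiny_archive_sets())
  d <- rep$demo
  expect_equal(d[primaryid == "5551", age_years], 72)
  expect_equal(d[primaryid == "6661", age_years], 0.5)  # 6 months
  expect_equal(d[primaryid == "5551", reporter_qualification], "physician")
  expect_equal(d[primaryid == "6661", reporter_qualification], "consumer")
  expect_equal(d[primaryid == "8881", reporter_qualification],
               "other_health_professional")
  expect_true(d[primaryid == "5552", fatal])
  expect_false(d[primaryid == "7771", fatal])
  # row conservation: every non-rejected DRUG/REAC row lands in one report
  expect_equal(nrow(rep$drug), 6L)
  expect_equal(nrow(rep$reac), 5L)
  expect_true(all(rep$drug$primaryid %in% d$primaryid))
})

test_that("orphan child rows go to the rejects log, never silently vanish", {
  demo <- parse_ascii_table(c("PRIMARYID$CASEID$FDA_DT", "1$10$20190101"),
                            "DEMO", "modern")
  drug <- parse_ascii_table(c("PRIMARYID$CASEID$DRUG_SEQ$ROLE_COD$DRUGNAME$PROD_AI$ROUTE",
                              "1$10$1$PS$X$X$ORAL",
                              "99$99$1$PS$Y$Y$ORAL"),
                            "DRUG", "modern")
  rep <- assemble_reports(list(demo, drug))
  expect_equal(nrow(rep$drug), 1L)
  expect_true(any(rep$rejects$reason == "orphan_key" &
                    rep$rejects$key == "99"))
})

test_that("route classification distinguishes intravenous, intraocular, unspecified", {
  rep <- assemble_reports(tiny_archive_sets())
  expect_equal(rep$drug[drugname == "CYRAMZA", route_class], "intravenous")
  expect_equal(rep$drug[drugname == "EYLEA", route_class], "intraocular")
  t <- parse_ascii_table(c("PRIMARYID$CASEID$DRUG_SEQ$ROLE_COD$DRUGNAME$PROD_AI$ROUTE",
                           "1$1$1$PS$A$A$", "2$2$1$PS$B$B$ORAL"),
                         "DRUG", "modern")
  demo <- parse_ascii_table(c("PRIMARYID$CASEID", "1$1", "2$2"), "DEMO", "modern")
  rep2 <- assemble_reports(list(demo, t))
  expect_equal(sort(rep2$drug$route_class), c("other", "unspecified"))
})

test_that("legacy ISR-keyed tables map onto the modern schema", {
  demo <- parse_ascii_table(c("ISR$CASE$FDA_DT$GNDR_COD$AGE$AGE_COD$OCC_COD",
                              "901$81$20080101$F$60$YR$MD"),
                            "DEMO", "legacy")
  reac <- parse_ascii_table(c("ISR$PT", "901$THROMBOSIS"), "REAC", "legacy")
  rep <- assemble_reports(list(demo, reac))
  expect_equal(rep$demo$primaryid, "901")
  expect_equal(rep$demo$caseid, "81")
  expect_equal(rep$demo$sex, "F")
  expect_equal(rep$demo$reporter_qualification, "physician")
  expect_equal(rep$reac$pt, "THROMBOSIS")
})

test_that("deduplication keeps the latest case version and is idempotent", {
  rep <- assemble_reports(tiny_archive_sets())
  dd <- deduplicate(rep)
  # case 555: the 2020 version survives the 2019 one
  expect_equal(dd$demo[caseid == "555", primaryid], "5552")
  expect_equal(nrow(dd$demo), length(unique(rep$demo$caseid)))
  # input unmodified
  expect_equal(nrow(rep$demo), 5L)
  # idempotence
  dd2 <- deduplicate(dd)
  expect_equal(dd2$demo$primaryid, dd$demo$primaryid)
  # output sorted by caseid
  expect_equal(dd$demo$caseid, sort(dd$demo$caseid))
})

test_that("dedup picks max (fda_dt, primaryid) per case, against a brute-force oracle", {
  set.seed(11)
  cases <- sprintf("c%02d", 1:5)
  demo_lines <- c("PRIMARYID$CASEID$FDA_DT")
  truth <- list()
  pid <- 100
  for (cs in cases) {
    fdas <- sample(c("20190101", "20190601", "20200101"), 3, replace = TRUE)
    pids <- as.character(pid + 1:3)
    pid <- pid + 10
    demo_lines <- c(demo_lines, paste(pids, cs, fdas, sep = "$"))
    # independent oracle: order by date then numeric id, take the max
    ord <- order(fdas, as.numeric(pids))
    truth[[cs]] <- pids[ord[3]]
  }
  dd <- deduplicate(assemble_reports(
    parse_ascii_table(demo_lines, "DEMO", "modern")))
  expect_equal(nrow(dd$demo), 5L)
  expect_equal(dd$demo$primaryid, unname(unlist(truth[dd$demo$caseid])))
})

test_that("reports with empty caseid are kept as flagged singletons", {
  demo <- parse_ascii_table(c("PRIMARYID$CASEID$FDA_DT",
                              "1$$20190101", "2$$20190101", "3$30$20190101"),
                            "DEMO", "modern")
  dd <- deduplicate(assemble_reports(demo))
  expect_equal(nrow(dd$demo), 3L)
  expect_equal(sum(dd$rejects$reason == "empty_caseid"), 2L)
})
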