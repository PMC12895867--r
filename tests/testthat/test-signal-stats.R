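test_that("ROR point estimates and intervals match direct formula evaluation", {
  r <- ror_estimate(contingency_table(10, 10, 10, 10))
  expect_equal(r$ror, 1.0)
  # exp(+/- 1.96 * sqrt(4/10))
  expect_equal(r$lower, exp(-1.96 * sqrt(0.4)), tolerance = 1e-12)
  expect_equal(r$upper, exp(+1.96 * sqrt(0.4)), tolerance = 1e-12)
  expect_equal(r$lower, 0.2895, tolerance = 1e-3)
  expect_equal(r$upper, 3.4543, tolerance = 1e-3)

  expect_equal(ror_estimate(contingency_table(20, 80, 10, 90))$ror, 2.25)
})

test_that("ROR equals the closed-form odds ratio over random nonzero tables", {
  set.seed(91)
  for (i in 1:300) {
    cl <- sample.int(30, 4, replace = TRUE)
    r <- ror_estimate(contingency_table(cl[1], cl[2], cl[3], cl[4]))
    expect_equal(r$ror, (cl[1] * cl[4]) / (cl[2] * cl[3]), tolerance = 1e-12)
    expect_false(r$corrected)
    expect_true(r$lower <= r$ror && r$ror <= r$upper)
  }
})

test_that("zero cells trigger the 0.5 correction only when present", {
  r <- ror_estimate(contingency_table(0, 10, 5, 85))
  expect_true(r$corrected)
  expect_equal(r$ror, (0.5 * 85.5) / (10.5 * 5.5), tolerance = 1e-12)
  r2 <- ror_estimate(contingency_table(0, 10, 5, 85), correct_zero = FALSE)
  expect_false(r2$evaluable)
  expect_true(is.na(r2$ror))
})

test_that("IC matches hand arithmetic and its sign tracks observed vs expected", {
  t <- contingency_table(20, 80, 10, 90)
  ic <- ic_estimate(t)
  expect_equal(ic$expected, 15)  # 100 * 30 / 200
  expect_equal(ic$ic, log2(20.5 / 15.5), tolerance = 1e-12)
  expect_equal(round(ic$ic, 4), 0.4034)

  # a = E gives IC exactly zero
  ic0 <- ic_estimate(contingency_table(10, 10, 10, 10))
  expect_equal(ic0$ic, 0)

  # a=4, E=1: frozen direct evaluation of the credibility bounds
  t2 <- contingency_table(4, 4, 21, 171)
  ic2 <- ic_estimate(t2)
  expect_equal(ic2$expected, 1)
  expect_equal(ic2$ic, log2(3), tolerance = 1e-12)
  expect_equal(ic2$lower, log2(3) - 3.3 / sqrt(4.5) - 2 / 4.5^1.5,
               tolerance = 1e-12)
  expect_equal(round(ic2$lower, 2), -0.18)

  # sign equivalence IC > 0  <=>  a > E
  set.seed(7)
  for (i in 1:200) {
    cl <- sample.int(30, 4, replace = TRUE)
    tt <- contingency_table(cl[1], cl[2], cl[3], cl[4])
    e <- ic_estimate(tt)
    expect_equal(e$ic > 0, cl[1] > e$expected)
  }
})

test_that("the gamma-posterior interval option brackets the point estimate", {
  t <- contingency_table(12, 88, 40, 860)
  g <- ic_estimate(t, method = "gamma")
  expect_lt(g$lower, g$ic)
  expect_gt(g$upper, g$ic)
  expect_equal(g$ic, ic_estimate(t)$ic)
})

test_that("signal evaluation enforces the three-report rule and dual threshold", {
  e2 <- evaluate_signal(contingency_table(2, 8, 100, 900))
  expect_false(e2$evaluated)
  expect_false(e2$signal)

  e3 <- evaluate_signal(contingency_table(10, 10, 10, 10))
  expect_true(e3$evaluated)
  expect_false(e3$signal)  # ROR lower bound ~0.29 <= 1

  # strong planted disproportionality at a = 200
  e4 <- evaluate_signal(contingency_table(200, 800, 1000, 12000))
  expect_true(e4$signal)
  expect_true(e4$ror_lower > 1 && e4$ic_lower > 0)

  # the flag always implies both thresholds
  set.seed(13)
  for (i in 1:100) {
    cl <- sample.int(500, 4, replace = TRUE)
    e <- evaluate_signal(contingency_table(cl[1], cl[2], cl[3], cl[4]))
    if (e$signal) expect_true(e$ror_lower > 1 && e$ic_lower > 0)
    if (!e$evaluated) expect_false(e$signal)
  }
})

test_that("contingency cells come from brute-force distinct-report counting", {
  u <- toy_universe(100, 10, 4, 20)
  t <- build_contingency(u, "drugX", "evt")
  expect_equal(c(t$a, t$b, t$c, t$d), c(4, 6, 16, 74))
  expect_error(build_contingency(u, "nosuch", "evt"), "unknown drug")
  expect_error(build_contingency(u, "drugX", "nosuch"), "unknown event")
})

test_that("transposing drug and event leaves the ROR invariant", {
  set.seed(23)
  for (i in 1:50) {
    cl <- sample.int(40, 4, replace = TRUE)
    r1 <- ror_estimate(contingency_table(cl[1], cl[2], cl[3], cl[4]))
    r2 <- ror_estimate(contingency_table(cl[1], cl[3], cl[2], cl[4]))
    expect_equal(r1$ror, r2$ror, tolerance = 1e-12)
  }
})

test_that("head-to-head comparisons are antisymmetric and threshold-consistent", {
  mk <- function(n, n_evt, drug) {
    data.table::data.table(primaryid = paste0(drug, seq_len(n)), drug = drug,
                           evt = seq_len(n) <= n_evt)
  }
  A <- mk(1000, 50, "A"); B <- mk(1000, 25, "B")
  h <- head_to_head(A, B, "evt")
  expect_equal(h$ror, (50 * 975) / (950 * 25), tolerance = 1e-12)
  expect_equal(round(h$ror, 3), 2.053)

  hr <- head_to_head(B, A, "evt")
  expect_equal(hr$ror, 1 / h$ror, tolerance = 1e-12)
  expect_equal(hr$ror_lower, 1 / h$ror_upper, tolerance = 1e-12)
  expect_equal(hr$ror_upper, 1 / h$ror_lower, tolerance = 1e-12)

  # identical event rates: ROR 1, no signal
  h0 <- head_to_head(mk(500, 40, "A"), mk(500, 40, "B"), "evt")
  expect_equal(h0$ror, 1)
  expect_false(h0$signal)

  # overlapping ids are a hard error
  expect_error(head_to_head(A, A, "evt"), "overlap")
})

test_that("the PT-level scan flags exactly the planted terms", {
  set.seed(77)
  n <- 4000; n_drug <- 400
  ids <- as.character(seq_len(n))
  drug <- c(rep("drugX", n_drug), rep("other", n - n_drug))
  pts <- c("PT_SIG1", "PT_SIG2", "PT_NULL1", "PT_NULL2", "PT_NULL3")
  prob <- function(pt, isdrug) {
    base <- 0.02
    if (pt %in% c("PT_SIG1", "PT_SIG2") && isdrug) base * 8 else base
  }
  reac <- data.table::rbindlist(lapply(pts, function(pt) {
    p <- ifelse(drug == "drugX", prob(pt, TRUE), prob(pt, FALSE))
    hit <- runif(n) < p
    data.table::data.table(primaryid = ids[hit], pt = pt)
  }))
  u <- structure(list(
    tab = data.table::data.table(primaryid = ids, drug = drug, fatal = FALSE,
                                 sex = "M", age_group = "18to64"),
    reac = reac, drugs = c("drugX", "other"), labels = character(),
    excluded_overlap = character()), class = "pv_universe")
  scan <- pt_level_scan(u, "drugX", pt_vocabulary = pts)
  expect_setequal(scan[signal == TRUE, pt], c("PT_SIG1", "PT_SIG2"))
  expect_equal(attr(scan, "n_signals"), 2L)
  # evaluated rows sorted by descending IC lower bound
  ev <- scan[evaluated == TRUE]
  expect_true(!is.unsorted(rev(ev$ic_lower)))
  # full audit list retained
  expect_equal(nrow(scan), 5L)
})
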