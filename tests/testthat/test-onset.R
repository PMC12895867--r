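test_that("onset intervals need full-precision dates and a non-negative span", {
  r <- onset_interval(
    event_tok = c("20190430", "20190201", "201904", "", "20190430"),
    start_tok = c("20190301", "20190301", "20190301", "20190301", "201903"))
  expect_equal(r$days, c(60L, NA, NA, NA, NA))
  expect_equal(r$excluded,
               c(NA, "negative_interval", "partial_precision", "missing",
                 "partial_precision"))
  # same-day onset counts as zero days, not an error
  expect_equal(onset_interval("20190301", "20190301")$days, 0L)
})

test_that("onset bins are closed integer ranges with exact boundaries", {
  expect_equal(as.character(bin_onset(c(0, 30, 31, 60, 61, 90, 91, 180, 181,
                                        365, 366, 1000))),
               c("0-30d", "0-30d", "31-60d", "31-60d", "61-90d", "61-90d",
                 "91-180d", "91-180d", "181-365d", "181-365d", ">365d",
                 ">365d"))
})

test_that("bin counts always add up to the number of binned onsets", {
  set.seed(3)
  for (i in 1:20) {
    days <- sample.int(800, sample(5:60, 1), replace = TRUE) - 1L
    expect_equal(sum(table(bin_onset(days))), length(days))
  }
})

test_that("median and quartiles follow the documented conventions", {
  expect_equal(median_iqr(c(1, 2, 3, 4))$median, 2.5)
  expect_equal(median_iqr(5), list(n = 1L, median = 5, q1 = 5, q3 = 5))
  x <- c(2, 4, 7, 11, 30, 55, 80)
  m <- median_iqr(x)
  expect_equal(m$q1, unname(quantile(x, 0.25, type = 7)))
  mt <- median_iqr(x, type = "tukey")
  expect_equal(c(mt$q1, mt$q3), fivenum(x)[c(2, 4)])
  expect_true(is.na(median_iqr(numeric())$median))
})

test_that("Mann-Whitney matches exact enumeration on small samples", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)  # 2/20 rank assignments are as extreme
  expect_equal(r$method, "exact")

  # identical samples: U = n^2/2, p = 1
  r2 <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r2$statistic, 8)
  expect_equal(r2$p_value, 1)

  # degenerate: everything tied
  expect_equal(mann_whitney(rep(2, 5), rep(2, 7))$p_value, 1.0)
})

test_that("Mann-Whitney is antisymmetric in its arguments", {
  set.seed(17)
  for (i in 1:20) {
    x <- sample.int(50, sample(3:15, 1), replace = TRUE)
    y <- sample.int(50, sample(3:15, 1), replace = TRUE)
    a <- mann_whitney(x, y); b <- mann_whitney(y, x)
    expect_equal(a$statistic + b$statistic, length(x) * length(y))
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  }
})

test_that("the normal-approximation branch agrees with the base-R oracle", {
  set.seed(29)
  for (i in 1:15) {
    x <- sample.int(30, 25, replace = TRUE)
    y <- sample.int(30, 20, replace = TRUE) + sample(0:4, 1)
    ours <- mann_whitney(x, y)
    expect_equal(ours$method, "normal_approx")
    ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE, exact = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis reproduces hand-ranked H and the base-R oracle", {
  r <- kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
  expect_equal(r$statistic, 7.2)
  expect_equal(r$df, 2L)

  expect_equal(kruskal_wallis(list(a = rep(4, 5), b = rep(4, 5)))$p_value, 1)
  expect_error(kruskal_wallis(list(a = 1:3, bad = numeric())), "bad")

  set.seed(31)
  for (i in 1:15) {
    g <- lapply(1:3, function(j) sample.int(20, sample(5:15, 1),
                                            replace = TRUE))
    ours <- kruskal_wallis(g)
    ref <- kruskal.test(g)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("two-group Kruskal-Wallis is the square of the standardized U", {
  set.seed(37)
  for (i in 1:10) {
    # continuous draws: no ties, so the identity is exact
    x <- rnorm(12); y <- rnorm(15)
    n1 <- 12; n2 <- 15; N <- n1 + n2
    u <- mann_whitney(x, y)$statistic
    z <- (u - n1 * n2 / 2) / sqrt(n1 * n2 * (N + 1) / 12)
    expect_equal(kruskal_wallis(list(x, y))$statistic, z^2,
                 tolerance = 1e-10)
  }
})

test_that("cumulative incidence steps are monotone and terminate at 100%", {
  ci <- cumulative_incidence(list(g = 5))
  expect_equal(ci$cum_pct, 100)
  expect_equal(ci$day, 5)

  ci2 <- cumulative_incidence(list(g = 1:10))
  expect_equal(ci2$cum_pct, seq(10, 100, 10))

  set.seed(41)
  ci3 <- cumulative_incidence(list(a = sample.int(400, 60, replace = TRUE),
                                   b = sample.int(100, 30, replace = TRUE)))
  for (g in c("a", "b")) {
    p <- ci3[group == g, cum_pct]
    expect_true(!is.unsorted(p))
    expect_equal(p[length(p)], 100)
  }
})
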