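test_that("a single binary covariate recovers the 2x2 table odds ratio", {
  # exposed 30/100 fatal, unexposed 20/100 fatal
  y <- c(rep(1, 30), rep(0, 70), rep(1, 20), rep(0, 80))
  x <- c(rep(1, 100), rep(0, 100))
  fit <- irls_logistic(cbind(1, x), y)
  expect_true(fit$converged)
  or <- (30 * 80) / (70 * 20)  # = 12/7
  expect_equal(unname(fit$coefficients$aOR[2]), or, tolerance = 1e-6)
  expect_equal(round(fit$coefficients$aOR[2], 4), 1.7143)

  # across random 2x2 configurations without zero cells, to 6 decimals
  set.seed(43)
  for (i in 1:20) {
    k <- sample(5:95, 2)
    n <- c(100, 120)
    yy <- c(rep(1, k[1]), rep(0, n[1] - k[1]), rep(1, k[2]),
            rep(0, n[2] - k[2]))
    xx <- c(rep(1, n[1]), rep(0, n[2]))
    f <- irls_logistic(cbind(1, xx), yy)
    oracle <- (k[1] * (n[2] - k[2])) / ((n[1] - k[1]) * k[2])
    expect_equal(unname(exp(f$coefficients$beta[2])), oracle,
                 tolerance = 1e-6)
  }
})

test_that("the null model intercept is the logit of the mean", {
  y <- c(rep(1, 40), rep(0, 60))
  fit <- irls_logistic(matrix(1, 100, 1), y)
  expect_equal(fit$coefficients$beta[1], log(0.4 / 0.6), tolerance = 1e-8)
})

test_that("IRLS agrees with the glm oracle on multivariable frames", {
  rows <- simulate_model_rows(4000, beta_exposure = log(1.5), seed = 47)
  frame <- build_model_frame(rows)
  fit <- fit_logistic(frame)
  ref <- glm(fit$formula, data = frame$data, family = binomial())
  expect_true(fit$converged)
  expect_equal(fit$coefficients$beta, unname(coef(ref)), tolerance = 1e-7)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
  expect_equal(fit$log_likelihood, as.numeric(logLik(ref)), tolerance = 1e-7)
})

test_that("the log-likelihood never decreases across IRLS iterations", {
  for (s in 1:5) {
    rows <- simulate_model_rows(600, beta_exposure = log(2), seed = 50 + s)
    fit <- fit_logistic(build_model_frame(rows))
    expect_true(all(diff(fit$ll_trace) >= -1e-9))
  }
})

test_that("row order never changes any reported number", {
  rows <- simulate_model_rows(1500, beta_exposure = log(1.3), seed = 59)
  f1 <- fit_logistic(build_model_frame(rows))
  set.seed(1); f2 <- fit_logistic(build_model_frame(rows[sample(.N)]))
  expect_equal(f1$coefficients$beta, f2$coefficients$beta, tolerance = 1e-9)
  expect_equal(f1$coefficients$se, f2$coefficients$se, tolerance = 1e-9)
})

test_that("complete separation is flagged, with no odds ratios reported", {
  x <- c(rep(0, 20), rep(1, 20))
  y <- x
  fit <- irls_logistic(cbind(1, x), y)
  expect_false(fit$converged)
  expect_true(fit$separation)
  expect_true(all(is.na(fit$coefficients$aOR)))
})

test_that("model frames declare reference levels and refuse degenerate exposure", {
  rows <- simulate_model_rows(300, beta_exposure = 0, seed = 61)
  frame <- build_model_frame(rows)
  expect_equal(levels(frame$data$sex)[1], "M")
  expect_equal(levels(frame$data$age_group)[1], "18to64")
  expect_equal(levels(frame$data$drug)[1], "bevacizumab")

  rows_allexp <- data.table::copy(rows)[, overall_TEE := TRUE]
  expect_error(build_model_frame(rows_allexp), "unexposed")
})

test_that("unknown demographic levels are kept unless complete-case is requested", {
  rows <- simulate_model_rows(400, beta_exposure = 0, seed = 67)
  rows$sex[1:40] <- "unknown"
  f <- build_model_frame(rows)
  expect_true("unknown" %in% levels(f$data$sex))
  fc <- build_model_frame(rows, complete_case = TRUE)
  expect_equal(nrow(fc$data), 360L)
})

test_that("the exposure aOR is invariant to the choice of reference levels", {
  rows <- simulate_model_rows(3000, beta_exposure = log(1.4), seed = 71)
  f1 <- fit_logistic(build_model_frame(rows))
  f2 <- fit_logistic(build_model_frame(rows, drug_levels = c("ramucirumab",
                                                             "bevacizumab")))
  a1 <- f1$coefficients[term == "exposureTRUE", aOR]
  a2 <- f2$coefficients[term == "exposureTRUE", aOR]
  expect_equal(a1, a2, tolerance = 1e-8)
})

test_that("the forest table reports crude percentages and flags unestimable strata", {
  rows <- simulate_model_rows(2500, beta_exposure = log(1.5), seed = 73)
  ft <- mortality_association(rows, subgroups = list(bevacizumab = "other"))
  expect_true(all(c("overall", "bevacizumab", "ramucirumab",
                    "bevacizumab/other") %in% ft$stratum))
  ov <- ft[stratum == "overall"]
  expect_true(ov$estimable)
  expect_equal(ov$fatal_pct_exposed,
               pct(sum(rows$fatal & rows$overall_TEE), sum(rows$overall_TEE)))
  # a stratum with no outcome variation is flagged, not dropped
  rows2 <- data.table::copy(rows)[drug == "ramucirumab", fatal := FALSE]
  ft2 <- mortality_association(rows2)
  expect_false(ft2[stratum == "ramucirumab", estimable])
  expect_true("ramucirumab" %in% ft2$stratum)
})

test_that("a planted null subgroup's confidence interval covers 1", {
  rows <- simulate_model_rows(6000, beta_exposure = 0, seed = 79)
  ft <- mortality_association(rows)
  ov <- ft[stratum == "overall"]
  expect_true(ov$aOR_lower <= 1 && 1 <= ov$aOR_upper)
})
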