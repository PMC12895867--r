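# Multivariable logistic model of fatal outcome: fatal ~ TEE exposure +
# sex + age group (+ drug in the pooled fit), fitted by iteratively
# reweighted least squares with Wald intervals, reported as adjusted odds
# ratios. Unknown sex/age are retained as explicit levels by default
# (dropping them would shrink the cohorts materially).

#' Build the mortality model frame
#'
#' One row per report from the drug cohorts: outcome is the fatal flag,
#' exposure is the overall thromboembolic-event label. Categorical
#' covariates are encoded with declared reference levels (exposure FALSE,
#' sex M, age 18to64, first drug in `drug_levels`); levels with no rows
#' are dropped and logged.
#'
#' @param rows stacked cohort rows from [select_cohort()] (one or several
#'   drugs)
#' @param drug_levels order of drug levels; the first is the reference
#'   (default: bevacizumab first when present)
#' @param complete_case drop rows with unknown sex or age instead of
#'   keeping "unknown" levels (default FALSE)
#' @return object of class `model_frame`: list with `data` (data.table
#'   with `outcome`, `exposure` and factor covariates) and
#'   `dropped_levels`
#' @export
build_model_frame <- function(rows, drug_levels = NULL,
                              complete_case = FALSE) {
  stopifnot(all(c("fatal", "overall_TEE", "sex", "age_group", "drug")
                %in% names(rows)))
  d <- data.table::data.table(
    outcome = rows$fatal,
    exposure = rows$overall_TEE,
    sex = as.character(rows$sex),
    age_group = as.character(rows$age_group),
    drug = as.character(rows$drug))
  if (complete_case) {
    d <- d[sex != "unknown" & age_group != "unknown"]
  }
  if (sum(d$exposure) == 0L || sum(!d$exposure) == 0L) {
    stop("model frame needs both exposed (TEE) and unexposed rows")
  }
  if (is.null(drug_levels)) {
    drug_levels <- unique(c(intersect("bevacizumab", d$drug), sort(unique(d$drug))))
  }
  lev <- list(sex = c("M", "F", "unknown"),
              age_group = c("18to64", "lt18", "ge65", "unknown"),
              drug = drug_levels)
  dropped <- character()
  for (v in names(lev)) {
    keep <- lev[[v]][lev[[v]] %in% unique(d[[v]])]
    gone <- setdiff(lev[[v]], keep)
    if (length(gone)) dropped <- c(dropped, paste0(v, "=", gone))
    d[[v]] <- factor(d[[v]], levels = keep)
  }
  structure(list(data = d, dropped_levels = dropped), class = "model_frame")
}

# Internal: Bernoulli log-likelihood at linear predictor eta.
logistic_loglik <- function(y, eta) {
  sum(y * eta - log1p(exp(eta)))
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood fit with step-halving (so the log-likelihood never
#' decreases across iterations), Wald standard errors from the inverse
#' observed information, and an explicit separation diagnostic: if a
#' fitted probability is within 1e-8 of 0 or 1 while its coefficient
#' diverges, the fit is flagged non-converged and no odds ratios are
#' reported.
#'
#' @param X numeric design matrix (including intercept column)
#' @param y 0/1 response vector
#' @param max_iter iteration cap (default 100)
#' @param score_tol convergence on the maximum absolute score (default 1e-8)
#' @param ll_tol convergence on the relative log-likelihood change
#'   (default 1e-10)
#' @return list with `coefficients` (term, beta, se, z, p_value, aOR,
#'   aOR_lower, aOR_upper), `converged`, `separation`, `iterations`,
#'   `log_likelihood`, `ll_trace`, `n_used`
#' @export
irls_logistic <- function(X, y, max_iter = 100L, score_tol = 1e-8,
                          ll_tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  p <- ncol(X)
  beta <- rep(0, p)
  eta <- drop(X %*% beta)
  ll <- logistic_loglik(y, eta)
  ll_trace <- ll
  converged <- FALSE
  separation <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving keeps the log-likelihood monotone
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- logistic_loglik(y, drop(X %*% cand))
      if (ll_new >= ll - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    beta <- beta + lam * step
    eta <- drop(X %*% beta)
    rel <- abs(ll_new - ll) / (abs(ll) + 1e-12)
    ll <- ll_new
    ll_trace <- c(ll_trace, ll)
    mu <- plogis(eta)
    if (any(mu < 1e-8 | mu > 1 - 1e-8) && max(abs(beta)) > 12) {
      separation <- TRUE
      break
    }
    if (max(abs(score)) < score_tol || rel < ll_tol) {
      converged <- TRUE
      break
    }
  }
  mu <- plogis(eta)
  info <- crossprod(X * (mu * (1 - mu)), X)
  cov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(cov), 0))
  z <- beta / se
  est <- data.table::data.table(
    term = colnames(X), beta = beta, se = se, z = z,
    p_value = 2 * pnorm(-abs(z)))
  if (converged && !separation) {
    est[, `:=`(aOR = exp(beta), aOR_lower = exp(beta - 1.96 * se),
               aOR_upper = exp(beta + 1.96 * se))]
  } else {
    est[, `:=`(aOR = NA_real_, aOR_lower = NA_real_, aOR_upper = NA_real_)]
  }
  list(coefficients = est, converged = converged && !separation,
       separation = separation, iterations = it, log_likelihood = ll,
       ll_trace = ll_trace, n_used = length(y))
}

#' Fit the mortality model on a model frame
#'
#' @param frame `model_frame` from [build_model_frame()]
#' @param covariates covariate names to adjust for (subset of
#'   `c("sex", "age_group", "drug")`)
#' @param ... passed to [irls_logistic()]
#' @return `regression_fit`: the [irls_logistic()] result plus the model
#'   formula used
#' @export
fit_logistic <- function(frame, covariates = c("sex", "age_group", "drug"),
                         ...) {
  stopifnot(inherits(frame, "model_frame"))
  d <- frame$data
  covariates <- covariates[vapply(covariates,
                                  function(v) nlevels(d[[v]]) > 1L,
                                  logical(1))]
  rhs <- paste(c("exposure", covariates), collapse = " + ")
  form <- stats::as.formula(paste("outcome ~", rhs))
  X <- stats::model.matrix(form, data = d)
  fit <- irls_logistic(X, d$outcome, ...)
  fit$formula <- form
  class(fit) <- "regression_fit"
  fit
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> %s | n=%d, logLik=%.2f, %s\n",
              deparse(x$formula), x$n_used, x$log_likelihood,
              if (x$converged) sprintf("converged in %d iter", x$iterations)
              else if (x$separation) "separation detected" else "not converged"))
  print(x$coefficients)
  invisible(x)
}

# Internal: one forest-table row for a stratum.
forest_row <- function(stratum, rows, covariates) {
  n <- nrow(rows)
  ne <- sum(rows$overall_TEE); nu <- n - ne
  pe <- pct(sum(rows$fatal & rows$overall_TEE), ne)
  pu <- pct(sum(rows$fatal & !rows$overall_TEE), nu)
  base <- data.table::data.table(
    stratum = stratum, n = n, n_exposed = ne,
    fatal_pct_exposed = pe, fatal_pct_unexposed = pu,
    aOR = NA_real_, aOR_lower = NA_real_, aOR_upper = NA_real_,
    p_value = NA_real_, estimable = FALSE)
  est <- tryCatch({
    frame <- build_model_frame(rows)
    fit <- fit_logistic(frame, covariates = covariates)
    if (!fit$converged) NULL else
      fit$coefficients[term == "exposureTRUE"]
  }, error = function(e) NULL)
  if (!is.null(est) && nrow(est) == 1L && is.finite(est$aOR)) {
    base[, `:=`(aOR = est$aOR, aOR_lower = est$aOR_lower,
                aOR_upper = est$aOR_upper, p_value = est$p_value,
                estimable = TRUE)]
  }
  base
}

#' Association between thromboembolic events and fatal outcome
#'
#' Forest-plot-ready table: the overall stratum (adjusted for sex, age
#' group and drug), one stratum per drug (sex and age), and optional
#' indication subgroups within a drug (sex and age, drug fixed). Strata
#' where the model cannot be fitted (no outcome variation, separation) are
#' emitted with `estimable = FALSE` rather than dropped.
#'
#' @param rows stacked cohort rows from [select_cohort()]
#' @param subgroups named list: drug -> indication groups to analyse as
#'   subgroups (default: none)
#' @return data.table, one row per stratum
#' @export
mortality_association <- function(rows, subgroups = list()) {
  out <- list(forest_row("overall", rows, c("sex", "age_group", "drug")))
  for (dg in sort(unique(rows$drug))) {
    out[[length(out) + 1L]] <-
      forest_row(dg, rows[drug == dg], c("sex", "age_group"))
  }
  for (dg in names(subgroups)) {
    for (ind in subgroups[[dg]]) {
      out[[length(out) + 1L]] <- forest_row(
        paste0(dg, "/", ind),
        rows[drug == dg & indication_group == ind],
        c("sex", "age_group"))
    }
  }
  data.table::rbindlist(out)
}
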