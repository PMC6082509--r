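#' Covariate set used for adjusted models
#'
#' Age plus the six coded comorbidities (heart failure, chronic kidney
#' disease, vascular disease, hypertension, diabetes, liver disease).
#' @return Character vector of column names.
#' @export
did_covariates <- function() {
  c("age", "heart_failure", "ckd", "vascular_disease", "hypertension",
    "diabetes", "liver_disease")
}

.did_data <- function(rows, outcome, covariates, cluster) {
  d <- as.data.frame(rows)
  need <- c(outcome, covariates, cluster, "site", "period")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  d <- d[, need, drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d$site <- factor(d$site, levels = c("control", "intervention"))
  d$period <- factor(d$period, levels = c("pre", "post"))
  d
}

.did_formula <- function(outcome, covariates, random = NULL) {
  rhs <- paste(c("site * period", covariates, random), collapse = " + ")
  stats::as.formula(paste(outcome, "~", rhs))
}

.interaction_name <- "siteintervention:periodpost"

#' Difference-in-differences logistic model with patient-level clustering
#'
#' Estimates the intervention effect on a binary outcome as the site-by-
#' period interaction in a marginal logistic model
#' `outcome ~ site + period + site:period + covariates`, fitted by
#' generalised estimating equations ([gee_logit()]) so the variance accounts
#' for repeated admissions of the same patient. The reported effect is the
#' exponentiated interaction coefficient — the ratio of post/pre odds ratios
#' at the intervention site versus the control site — with a robust Wald
#' confidence interval and p-value.
#'
#' In the saturated unadjusted case with independent clusters the
#' interaction odds ratio equals exactly the ratio of the two unadjusted
#' 2x2 odds ratios.
#'
#' @param rows Cohort rows containing `site`, `period`, the outcome, the
#'   covariates and the cluster key.
#' @param outcome Name of a logical/0-1 column.
#' @param covariates Character vector of adjustment columns (default
#'   [did_covariates()]; use `NULL` for the unadjusted model).
#' @param cluster Cluster key column (default `"patient_id"`).
#' @param corstr Working correlation passed to [gee_logit()].
#' @param level Confidence level (default 0.95).
#' @return Object of class `did_result`: `interaction_or`, `ci_low`,
#'   `ci_high`, `p_value`, `log_or`, `se`, `n_obs`, `n_clusters`,
#'   `converged`, `fit_ok`, and the underlying `fit`.
#' @export
did_binary <- function(rows, outcome, covariates = did_covariates(),
                       cluster = "patient_id",
                       corstr = c("exchangeable", "independence"),
                       level = 0.95) {
  corstr <- match.arg(corstr)
  d <- .did_data(rows, outcome, covariates, cluster)
  d[[outcome]] <- as.numeric(d[[outcome]])
  fit <- gee_logit(.did_formula(outcome, covariates), d, id = cluster,
                   corstr = corstr)
  est <- fit$coefficients[.interaction_name]
  se <- sqrt(diag(fit$vcov))[.interaction_name]
  fit_ok <- fit$converged && is.finite(est) && is.finite(se) &&
    abs(est) < 15
  if (!fit_ok) {
    warning("difference-in-differences fit did not converge cleanly; ",
            "estimates may reflect separation", call. = FALSE)
  }
  z <- qnorm(1 - (1 - level) / 2)
  structure(list(
    interaction_or = exp(unname(est)),
    ci_low = exp(unname(est - z * se)),
    ci_high = exp(unname(est + z * se)),
    p_value = 2 * pnorm(-abs(unname(est / se))),
    log_or = unname(est), se = unname(se),
    outcome = outcome, link = "logistic",
    n_obs = fit$n_obs, n_clusters = fit$n_clusters,
    converged = fit$converged, fit_ok = fit_ok, fit = fit
  ), class = "did_result")
}

#' Difference-in-differences linear mixed model for continuous outcomes
#'
#' Same fixed-effect structure as [did_binary()] with a patient-level random
#' intercept (fitted with `lme4::lmer`). A singular random-effect fit —
#' inevitable when every patient has a single admission — is flagged and the
#' model falls back to ordinary least squares with a message; in that
#' degenerate case the estimates equal OLS by construction. Inference is a
#' normal-approximation Wald interval on the interaction coefficient.
#'
#' @inheritParams did_binary
#' @param outcome Name of a numeric column (e.g. peak creatinine rise,
#'   length of stay).
#' @return Object of class `did_result` with `interaction_effect` (additive,
#'   on the outcome scale) in place of an odds ratio.
#' @export
did_continuous <- function(rows, outcome, covariates = did_covariates(),
                           cluster = "patient_id", level = 0.95) {
  d <- .did_data(rows, outcome, covariates, cluster)
  singular <- FALSE
  fit <- tryCatch({
    f <- .did_formula(outcome, covariates,
                      random = paste0("(1 | ", cluster, ")"))
    m <- suppressMessages(suppressWarnings(lme4::lmer(f, data = d)))
    if (lme4::isSingular(m)) { singular <- TRUE; NULL } else m
  }, error = function(e) { singular <<- TRUE; NULL })
  if (is.null(fit)) {
    message("random-intercept fit singular; falling back to the ",
            "independence (OLS) model")
    fit <- stats::lm(.did_formula(outcome, covariates), data = d)
    est <- coef(fit)[.interaction_name]
    se <- sqrt(diag(stats::vcov(fit)))[.interaction_name]
  } else {
    est <- lme4::fixef(fit)[.interaction_name]
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))[.interaction_name]
  }
  z <- qnorm(1 - (1 - level) / 2)
  structure(list(
    interaction_effect = unname(est),
    ci_low = unname(est - z * se), ci_high = unname(est + z * se),
    p_value = 2 * pnorm(-abs(unname(est / se))),
    se = unname(se), outcome = outcome, link = "identity",
    n_obs = nrow(d), n_clusters = length(unique(d[[cluster]])),
    singular = singular, fit_ok = is.finite(est) && is.finite(se),
    fit = fit
  ), class = "did_result")
}

#' @export
print.did_result <- function(x, ...) {
  if (x$link == "logistic") {
    cat(sprintf(
      "DiD interaction OR for %s: %.3f (%.3f-%.3f), p = %.3g\n",
      x$outcome, x$interaction_or, x$ci_low, x$ci_high, x$p_value))
  } else {
    cat(sprintf(
      "DiD interaction effect on %s: %.3f (%.3f-%.3f), p = %.3g\n",
      x$outcome, x$interaction_effect, x$ci_low, x$ci_high, x$p_value))
  }
  cat(sprintf("n = %d admissions, %d patients; p-values are unadjusted\n",
              x$n_obs, x$n_clusters))
  invisible(x)
}
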