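# Estimands and tests.
#
# The principal causal effect on factor q at visit j within stratum m is the
# fixed-effect contrast (x_qj(1) - x_qj(0))' beta_qm: random effects and the
# level-2 disturbance have mean zero within a stratum, so only the treatment
# columns of the design contribute. The CACE is the complier-stratum PCE; it
# is identically zero for never-takers (exclusion restriction). Delta-method
# standard errors use the fitted covariance of beta.

estimand_contrast <- function(spec, stratum, q, visit) {
  if (visit < 0 || visit > spec$J1 - 1L) stop("visit outside the schedule")
  X1 <- build_designs(spec, arm = 1, receipt = if (stratum == "c") 1 else 0,
                      stratum = stratum)$X
  X0 <- build_designs(spec, arm = 0, receipt = 0, stratum = stratum)$X
  row <- (q - 1L) * spec$J1 + visit + 1L
  drop(X1[row, ] - X0[row, ])
}

one_estimand <- function(fit, q, stratum, visit, conf_level = 0.95, exact_quantile = FALSE) {
  spec <- fit$spec
  cvec <- estimand_contrast(spec, stratum, q, visit)
  beta <- fit$params$beta[[stratum]]
  est <- sum(cvec * beta)
  se <- NA_real_
  if (!is.null(fit$vcov) && length(beta)) {
    idx <- match(names(beta), colnames(fit$vcov))
    Vb <- fit$vcov[idx, idx, drop = FALSE]
    se <- sqrt(max(drop(t(cvec) %*% Vb %*% cvec), 0))
  }
  z <- if (is.na(se) || se == 0) { if (est == 0) 0 else NA_real_ } else est / se
  p <- if (is.na(z)) NA_real_ else if (z == 0) 1 else 2 * pnorm(-abs(z))
  zq <- if (exact_quantile) qnorm(1 - (1 - conf_level) / 2) else 1.96
  tibble::tibble(
    factor = q, stratum = stratum, visit = visit, time = spec$times[visit + 1L],
    estimate = est, std.error = se, statistic = z, p.value = p,
    conf.low = est - zq * se, conf.high = est + zq * se
  )
}

#' Principal causal effects on the latent factors
#'
#' @param fit An [mcace_fit()].
#' @param stratum `"c"` or `"n"`; never-taker effects are structurally zero.
#' @param visit Visit index (0-based); defaults to every post-baseline visit.
#' @param factors Factor indices (default all).
#' @param conf_level Confidence level.
#' @param exact_quantile Use the exact normal quantile instead of 1.96.
#' @return Tibble of class `mcace_estimands` with one row per
#'   (factor, visit): estimate, delta-method SE, Wald statistic and p-value,
#'   confidence interval.
#' @export
pce <- function(fit, stratum = c("c", "n"), visit = NULL, factors = NULL,
                conf_level = 0.95, exact_quantile = FALSE) {
  stratum <- match.arg(stratum)
  spec <- fit$spec
  visit <- visit %||% seq_len(spec$J1 - 1L)
  factors <- factors %||% seq_len(spec$Q)
  out <- dplyr::bind_rows(purrr::map(factors, function(q) {
    dplyr::bind_rows(purrr::map(visit, function(j) {
      one_estimand(fit, q, stratum, j, conf_level, exact_quantile)
    }))
  }))
  class(out) <- c("mcace_estimands", class(out))
  out
}

#' Complier average causal effects on the latent factors
#'
#' The CACE at visit j on factor q is the complier-stratum PCE, i.e. the
#' treatment contrast applied to the complier fixed effects. With the
#' quadratic specification the contrast at time t is
#' `t * beta[D:t] + t^2 * beta[D:t2]`.
#'
#' @inheritParams pce
#' @export
cace <- function(fit, visit = NULL, factors = NULL, conf_level = 0.95,
                 exact_quantile = FALSE) {
  pce(fit, stratum = "c", visit = visit, factors = factors,
      conf_level = conf_level, exact_quantile = exact_quantile)
}

#' Two-sided Wald test
#'
#' @param estimate,se Estimate and its standard error (`se > 0`).
#' @return Tibble with `statistic` (z) and `p.value`.
#' @export
wald_test <- function(estimate, se) {
  if (any(se <= 0)) stop("standard errors must be positive")
  z <- estimate / se
  tibble::tibble(statistic = z, p.value = 2 * pnorm(-abs(z)))
}

#' Global likelihood-ratio test of nested MCACE fits
#'
#' The global test of no treatment effect on any latent factor compares the
#' full fit with a fit in which the treatment terms are dropped from the
#' complier model. A single test replaces K Bonferroni-corrected per-outcome
#' tests.
#'
#' @param fit_full,fit_null Fits of nested specifications on the same data.
#' @param df Degrees of freedom (default: difference in free parameter
#'   counts).
#' @param alpha Reporting level.
#' @return Tibble with `statistic`, `df`, `p.value`, `alpha`, `reject`.
#' @export
global_lrt <- function(fit_full, fit_null, df = NULL, alpha = 0.05) {
  if (fit_full$n_subjects != fit_null$n_subjects) {
    stop("fits are not on the same data (subject counts differ)")
  }
  df <- df %||% (fit_full$n_free - fit_null$n_free)
  if (df <= 0) stop("the null model is not nested in the full model")
  stat <- 2 * (fit_full$loglik - fit_null$loglik)
  if (stat < -1e-6) {
    # optimizer failure on the full model: refit once from the null optimum
    start <- embed_params(fit_null$params, fit_null$spec, fit_full$spec)
    refit <- mcace_fit(fit_full$data, fit_full$spec, start = start,
                       control = modifyList(fit_full$control, list(n_restarts = 1)),
                       vcov = "none")
    if (refit$loglik > fit_full$loglik) fit_full <- refit
    stat <- 2 * (fit_full$loglik - fit_null$loglik)
  }
  stat <- max(stat, 0)
  tibble::tibble(statistic = stat, df = df,
                 p.value = pchisq(stat, df, lower.tail = FALSE),
                 alpha = alpha, reject = pchisq(stat, df, lower.tail = FALSE) < alpha)
}

# Map a null-spec parameter set into a fuller spec (absent coefficients 0).
embed_params <- function(params, spec_from, spec_to) {
  out <- par_template(spec_to)
  out$lambda0 <- params$lambda0
  out$Lambda <- params$Lambda
  out$xi <- params$xi
  out$tau2 <- params$tau2
  out$eta[names(params$eta)] <- params$eta
  for (m in c("c", "n")) {
    common <- intersect(names(out$beta[[m]]), names(params$beta[[m]]))
    out$beta[[m]][] <- 0
    out$beta[[m]][common] <- params$beta[[m]][common]
  }
  for (q in seq_along(out$Sigma_v)) {
    rf <- spec_from$random[[q]]; rt <- spec_to$random[[q]]
    if (length(rf) && length(rt)) {
      ix <- match(intersect(rt, rf), rt)
      jx <- match(intersect(rt, rf), rf)
      S <- diag(0.1, length(rt))
      S[ix, ix] <- params$Sigma_v[[q]][jx, jx]
      out$Sigma_v[[q]] <- S
    }
  }
  out
}

#' Drop level-2 terms from a specification
#'
#' Convenience for building the null model of the global treatment-effect
#' test, e.g. `spec_drop_terms(spec, "D:t")`.
#'
#' @param spec An [mcace_spec()].
#' @param terms Terms removed from the fixed-effect list (and from the random
#'   terms if present).
#' @export
spec_drop_terms <- function(spec, terms) {
  lv <- spec$level2
  lv$fixed <- setdiff(lv$fixed, terms)
  lv$random <- lapply(spec$random, function(r) setdiff(r, terms))
  mcace_spec(spec$K, spec$Q, times = spec$times, loading = spec$loading,
             level2 = lv, compliance_covariates = setdiff(spec$compliance_covariates, "(Intercept)"),
             eps_var = spec$eps_var, outcome_names = spec$outcome_names)
}

#' Compare fitted models by information criteria
#'
#' @param ... Named `mcace_fit` objects (or a single list of them) fitted to
#'   the same data.
#' @return Tibble (model, logLik, n_free, AIC, BIC) sorted by AIC, ties broken
#'   by BIC and then by fewer parameters.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1L]], "mcace_fit")) fits <- fits[[1L]]
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  ns <- vapply(fits, function(f) f$n_subjects, 1)
  if (length(unique(ns)) > 1L) stop("fits were not computed on the same data (subject counts differ)")
  out <- tibble::tibble(
    model = names(fits),
    logLik = vapply(fits, function(f) f$loglik, 1),
    n_free = vapply(fits, function(f) f$n_free, 1),
    AIC = vapply(fits, function(f) f$aic, 1),
    BIC = vapply(fits, function(f) f$bic, 1)
  )
  dplyr::arrange(out, .data$AIC, .data$BIC, .data$n_free)
}

#' @importFrom rlang .data
NULL
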