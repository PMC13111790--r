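# Per-outcome univariate comparator and domain-score analysis.
#
# The univariate CACE analysis fits each endpoint separately with the K = 1
# specialization of the principal-stratification machinery: measurement
# intercept, random intercept, level-2 terms t, t2, D:t (optionally D:t2),
# random slope in t, and a free residual variance (the level-2 disturbance is
# absorbed — at K = 1 the two iid per-visit noises are not separately
# identifiable, so the disturbance variance is set to 0 and the loading fixed
# at 1). The control-arm compliance mixture is identical to the multivariate
# model's. The family-wise decision Bonferroni-adjusts the K per-outcome
# likelihood-ratio tests.

#' Specification of the single-outcome comparator model
#'
#' @param terms Level-2 fixed terms (default `t`, `t2`, `D:t`).
#' @param random Random-effect terms (default slope in `t`).
#' @param times Visit schedule.
#' @param compliance_covariates Compliance-model covariate names.
#' @param outcome_name Outcome column name.
#' @return An [mcace_spec()] with K = 1, Q = 1, loading fixed at 1 and
#'   disturbance variance 0.
#' @export
univariate_spec <- function(terms = c("t", "t2", "D:t"), random = "t",
                            times = c(0, 1, 2), compliance_covariates = character(0),
                            outcome_name = "y") {
  mcace_spec(
    K = 1, Q = 1, times = times,
    loading = loading_mask(matrix(FALSE, 1, 1), fixed_value = 1),
    level2 = level2_terms(fixed = terms, random = random, baseline_balance = TRUE),
    compliance_covariates = compliance_covariates,
    eps_var = 0, outcome_names = outcome_name
  )
}

#' Univariate CACE fit for one endpoint
#'
#' Fits the single-outcome principal-stratification mixed model to outcome
#' `outcome`, together with the nested no-treatment-effect model, and returns
#' the treatment-effect likelihood-ratio test (the coefficient of `D:t`, plus
#' any other treatment terms present).
#'
#' @param data Long trial tibble (or `mcace_data`).
#' @param outcome Outcome column name or index.
#' @param terms,random As in [univariate_spec()].
#' @param covariates Optional baseline covariate table.
#' @param control A [fit_control()].
#' @param vcov Covariance method for the full fit.
#' @return List of class `univariate_fit`: `outcome`, `fit`, `fit_null`,
#'   `lrt` (tibble), and `cace` at the final visit.
#' @export
fit_univariate <- function(data, outcome, terms = c("t", "t2", "D:t"),
                           random = "t", covariates = NULL,
                           control = fit_control(n_restarts = 1),
                           vcov = "original-fd") {
  d <- as_mcace_data(data, covariates)
  if (is.numeric(outcome)) outcome <- d$outcome_names[outcome]
  k <- match(outcome, d$outcome_names)
  if (is.na(k)) stop("no such outcome: ", outcome)
  d1 <- d
  keep <- (k - 1L) * d$J1 + seq_len(d$J1)
  d1$Y <- d$Y[, keep, drop = FALSE]
  d1$K <- 1L
  d1$outcome_names <- outcome
  if (any(rowSums(!is.na(d1$Y)) == 0L)) {
    ok <- rowSums(!is.na(d1$Y)) > 0L
    d1$Y <- d1$Y[ok, , drop = FALSE]
    d1$arm <- d1$arm[ok]; d1$receipt <- d1$receipt[ok]
    d1$W <- d1$W[ok, , drop = FALSE]; d1$id <- d1$id[ok]; d1$N <- sum(ok)
  }
  spec <- univariate_spec(terms, random, times = d$times, outcome_name = outcome)
  spec_null <- spec_drop_terms(spec, terms[term_involves_D(terms)])
  fit <- mcace_fit(d1, spec, control = control, vcov = vcov)
  fit0 <- mcace_fit(d1, spec_null, control = control, vcov = "none")
  lrt <- global_lrt(fit, fit0)
  structure(
    list(outcome = outcome, fit = fit, fit_null = fit0, lrt = lrt,
         cace = cace(fit, visit = d$J1 - 1L)),
    class = "univariate_fit"
  )
}

#' @export
print.univariate_fit <- function(x, ...) {
  cat("<univariate_fit>", x$outcome, "\n")
  cat(sprintf("  CACE at final visit: %.3f (SE %.3f)\n",
              x$cace$estimate, x$cace$std.error))
  cat(sprintf("  LRT of no treatment effect: stat %.3f, df %d, p %.4f\n",
              x$lrt$statistic, x$lrt$df, x$lrt$p.value))
  invisible(x)
}

#' Univariate CACE analysis of every endpoint
#'
#' @inheritParams fit_univariate
#' @param alpha Family-wise level for the Bonferroni decision.
#' @return Tibble with one row per outcome (CACE at the final visit, SE,
#'   LRT statistic and p-value, convergence) plus attributes
#'   `reject_any` (Bonferroni decision) and `fits`.
#' @export
univariate_cace_all <- function(data, terms = c("t", "t2", "D:t"), random = "t",
                                covariates = NULL, control = fit_control(n_restarts = 1),
                                alpha = 0.05) {
  d <- as_mcace_data(data, covariates)
  fits <- purrr::map(d$outcome_names, function(k) {
    tryCatch(fit_univariate(d, k, terms, random, control = control, vcov = "none"),
             error = function(e) NULL)
  })
  rows <- purrr::map2(fits, d$outcome_names, function(f, k) {
    if (is.null(f)) {
      return(tibble::tibble(outcome = k, estimate = NA_real_, p.value = NA_real_,
                            statistic = NA_real_, converged = FALSE))
    }
    tibble::tibble(outcome = k, estimate = f$cace$estimate,
                   statistic = f$lrt$statistic, p.value = f$lrt$p.value,
                   converged = f$fit$converged && f$fit_null$converged)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "reject_any") <- bonferroni_reject(out$p.value[!is.na(out$p.value)], alpha,
                                               K = nrow(out))
  attr(out, "fits") <- fits
  out
}

#' Bonferroni family-wise decision
#'
#' Rejects the global null when any of the K per-outcome p-values falls below
#' `alpha / K`.
#'
#' @param p Vector of per-test p-values.
#' @param alpha Family-wise level.
#' @param K Number of tests (default `length(p)`; supply explicitly when some
#'   tests failed to produce a p-value).
#' @return Logical.
#' @export
bonferroni_reject <- function(p, alpha = 0.05, K = length(p)) {
  stopifnot(K >= 1)
  any(p < alpha / K, na.rm = TRUE)
}

#' Missing-aware domain scores
#'
#' Averages the member outcomes of each group at each subject-visit, using
#' the available (non-missing) members.
#'
#' @param data Long trial tibble.
#' @param groups Named list of outcome index (or name) vectors partitioning a
#'   subset of the outcomes.
#' @return Long tibble with one score column per group.
#' @export
domain_scores <- function(data, groups) {
  d <- as_mcace_data(data)
  long <- as_long_tibble(d)
  if (is.null(names(groups))) names(groups) <- paste0("score", seq_along(groups))
  out <- long[, c("id", "arm", "receipt", "visit", "time")]
  for (g in names(groups)) {
    members <- groups[[g]]
    if (length(members) == 0L) stop("empty domain group: ", g)
    if (is.numeric(members)) members <- d$outcome_names[members]
    out[[g]] <- rowMeans(as.matrix(long[, members, drop = FALSE]), na.rm = TRUE)
    out[[g]][is.nan(out[[g]])] <- NA_real_
  }
  out
}

#' Domain-score univariate CACE analysis
#'
#' Builds missing-aware average scores per group and runs the univariate
#' principal-stratification analysis on each; the CACE is reported at the
#' requested visit.
#'
#' @inheritParams fit_univariate
#' @param groups Named list of outcome groupings (see [domain_scores()]).
#' @param visit Visit at which to report the CACE (default final).
#' @return Tibble with one row per domain score (estimate, SE, Wald z and p).
#' @export
domain_score_analysis <- function(data, groups, terms = c("t", "t2", "D:t"),
                                  random = "t", covariates = NULL, visit = NULL,
                                  control = fit_control(n_restarts = 1)) {
  scored <- domain_scores(data, groups)
  d <- as_mcace_data(scored, covariates)
  visit <- visit %||% (d$J1 - 1L)
  rows <- purrr::map(names(groups), function(g) {
    f <- fit_univariate(d, g, terms, random, control = control)
    cc <- cace(f$fit, visit = visit)
    tibble::tibble(score = g, visit = visit, estimate = cc$estimate,
                   std.error = cc$std.error, statistic = cc$statistic,
                   p.value = cc$p.value)
  })
  dplyr::bind_rows(rows)
}
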