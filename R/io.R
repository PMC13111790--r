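# Configuration and data file I/O.
#
# Scenarios (model structure + true parameter values + trial settings) are
# stored as YAML; trial data as delimited long-format text with a separate
# per-subject covariate table.

spec_to_list <- function(spec) {
  list(
    K = spec$K, Q = spec$Q, times = spec$times,
    loading = list(
      mode = spec$loading$mode,
      mask = apply(spec$loading$mask, 1, as.integer, simplify = FALSE),
      fixed = apply(spec$loading$fixed, 1, as.numeric, simplify = FALSE),
      anchors = spec$loading$anchors
    ),
    level2 = list(fixed = spec$level2$fixed,
                  random = spec$random,
                  baseline_balance = spec$level2$baseline_balance),
    compliance_covariates = setdiff(spec$compliance_covariates, "(Intercept)"),
    eps_var = spec$eps_var,
    outcome_names = spec$outcome_names
  )
}

spec_from_list <- function(x) {
  mask <- do.call(rbind, lapply(x$loading$mask, as.logical))
  fixed <- do.call(rbind, lapply(x$loading$fixed, as.numeric))
  mcace_spec(
    K = x$K, Q = x$Q, times = as.numeric(x$times),
    loading = loading_mask(mask, fixed, mode = x$loading$mode,
                           anchors = as.integer(x$loading$anchors)),
    level2 = level2_terms(fixed = as.character(x$level2$fixed),
                          random = lapply(x$level2$random, as.character),
                          baseline_balance = isTRUE(x$level2$baseline_balance)),
    compliance_covariates = as.character(x$compliance_covariates %||% character(0)),
    eps_var = x$eps_var %||% 1,
    outcome_names = as.character(x$outcome_names)
  )
}

#' Write a simulation scenario to YAML
#'
#' Every true parameter is listed by name; no scenario values live in code.
#'
#' @param scenario A [sim_scenario()].
#' @param path Output file.
#' @export
write_scenario <- function(scenario, path) {
  p <- scenario$params
  obj <- list(
    spec = spec_to_list(scenario$spec),
    params = list(
      lambda0_c = as.numeric(p$lambda0[, "c"]),
      lambda0_n = as.numeric(p$lambda0[, "n"]),
      loadings = as.numeric(p$Lambda[scenario$spec$loading$mask]),
      beta_c = as.list(p$beta$c), beta_n = as.list(p$beta$n),
      xi_c = as.numeric(p$xi[, "c"]), xi_n = as.numeric(p$xi[, "n"]),
      tau2_c = as.numeric(p$tau2[, "c"]), tau2_n = as.numeric(p$tau2[, "n"]),
      sigma_v = lapply(p$Sigma_v, function(S) apply(S, 1, as.numeric, simplify = FALSE)),
      eta = as.list(p$eta)
    ),
    trial = list(n_subjects = scenario$n_subjects,
                 allocation = scenario$allocation,
                 fixed_allocation = scenario$fixed_allocation,
                 missingness = if (is.matrix(scenario$missingness)) {
                   apply(scenario$missingness, 1, as.numeric, simplify = FALSE)
                 },
                 compliance_covariate = scenario$compliance_covariate)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a simulation scenario from YAML
#' @param path YAML file written by [write_scenario()] (or hand-authored in
#'   the same schema).
#' @return A [sim_scenario()].
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  spec <- spec_from_list(x$spec)
  params <- par_template(spec)
  pp <- x$params
  params$lambda0[, "c"] <- as.numeric(pp$lambda0_c)
  params$lambda0[, "n"] <- as.numeric(pp$lambda0_n)
  params$Lambda[spec$loading$mask] <- as.numeric(pp$loadings)
  params$beta$c[names(pp$beta_c)] <- as.numeric(unlist(pp$beta_c))
  params$beta$n[names(pp$beta_n)] <- as.numeric(unlist(pp$beta_n))
  params$xi[, "c"] <- as.numeric(pp$xi_c); params$xi[, "n"] <- as.numeric(pp$xi_n)
  params$tau2[, "c"] <- as.numeric(pp$tau2_c); params$tau2[, "n"] <- as.numeric(pp$tau2_n)
  params$Sigma_v <- purrr::map2(pp$sigma_v, params$Sigma_v, function(rows, S) {
    M <- do.call(rbind, lapply(rows, as.numeric))
    if (length(S)) M else S
  })
  params$eta[names(pp$eta)] <- as.numeric(unlist(pp$eta))
  tr <- x$trial
  sim_scenario(spec, params,
               n_subjects = tr$n_subjects,
               allocation = tr$allocation %||% 0.5,
               missingness = if (!is.null(tr$missingness)) {
                 do.call(rbind, lapply(tr$missingness, as.numeric))
               },
               compliance_covariate = tr$compliance_covariate,
               fixed_allocation = isTRUE(tr$fixed_allocation))
}

#' Read long-format trial data from delimited text
#'
#' @param outcomes_path CSV with columns `id`, `arm`, `receipt`, `visit`,
#'   optional `time`, and the outcome columns; empty cells are missing.
#' @param covariates_path Optional CSV with `id` plus baseline covariates.
#' @return An `mcace_data` object.
#' @export
read_trial_data <- function(outcomes_path, covariates_path = NULL) {
  outcomes <- utils::read.csv(outcomes_path)
  covariates <- if (!is.null(covariates_path)) utils::read.csv(covariates_path)
  mcace_data(outcomes, covariates)
}

#' Write a simulated trial to delimited text
#'
#' @param sim An `mcace_sim` (or a long tibble).
#' @param outcomes_path,covariates_path Output CSV paths.
#' @export
write_trial_data <- function(sim, outcomes_path, covariates_path = NULL) {
  df <- if (inherits(sim, "mcace_sim")) sim$data else sim
  utils::write.csv(df, outcomes_path, row.names = FALSE)
  if (!is.null(covariates_path) && inherits(sim, "mcace_sim")) {
    utils::write.csv(sim$covariates, covariates_path, row.names = FALSE)
  }
  invisible(outcomes_path)
}

#' Human-readable estimate report
#'
#' Writes the treatment-effect coefficient table and the per-factor CACE
#' summary of a fit in a fixed-width layout (estimate, SE, 95% CI, p-value).
#'
#' @param fit An [mcace_fit()].
#' @param file Connection or path (default: print to console).
#' @param visit Visit at which to report CACEs (default final).
#' @export
report_fit <- function(fit, file = stdout(), visit = NULL) {
  spec <- fit$spec
  visit <- visit %||% (spec$J1 - 1L)
  td <- tidy.mcace_fit(fit)
  trt <- td[grepl("^beta\\[c", td$term) &
              vapply(td$term, function(s) any(vapply(TERM_VOCAB[term_involves_D(TERM_VOCAB)],
                                                     function(v) grepl(v, s, fixed = TRUE), TRUE)), TRUE), ]
  lines <- c(
    sprintf("Latent-factor MCACE fit: K = %d outcomes, Q = %d factors, N = %d subjects",
            spec$K, spec$Q, fit$n_subjects),
    sprintf("logLik %.3f   AIC %.2f   BIC %.2f", fit$loglik, fit$aic, fit$bic),
    "",
    "Treatment-effect coefficients (compliers):",
    sprintf("  %-18s %9s %9s %19s %8s", "parameter", "estimate", "SE", "95% CI", "p"),
    vapply(seq_len(nrow(trt)), function(i) {
      sprintf("  %-18s %9.3f %9.3f   (%7.3f, %7.3f) %8.3f",
              trt$term[i], trt$estimate[i], trt$std.error[i],
              trt$conf.low[i], trt$conf.high[i], trt$p.value[i])
    }, ""),
    "",
    sprintf("CACE on each latent factor at visit %d (t = %g):", visit, spec$times[visit + 1]),
    { cc <- cace(fit, visit = visit)
      vapply(seq_len(nrow(cc)), function(i) {
        sprintf("  factor %d: %8.3f (SE %6.3f)   95%% CI (%7.3f, %7.3f)   p = %.3f",
                cc$factor[i], cc$estimate[i], cc$std.error[i],
                cc$conf.low[i], cc$conf.high[i], cc$p.value[i])
      }, "") }
  )
  writeLines(lines, con = file)
  invisible(lines)
}
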