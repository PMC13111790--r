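# Replicated-experiment harness: power, type-I error, recovery/calibration.
#
# Replicates are seeded as base_seed + replicate index within each grid cell,
# so a cell's replicates can be split across invocations and pooled without
# changing the result, and the tables are bit-reproducible. Rejection rates
# are computed over converged replicates, with failure counts reported.

#' Experiment grid for power / type-I studies
#'
#' @param n_subjects Sample sizes.
#' @param p_compliance Compliance rates.
#' @param effect Complier treatment-by-time coefficients (0 rows measure the
#'   type-I error).
#' @param n_replicates Replicates per cell.
#' @param base_seed Base seed; replicate i uses `base_seed + i`.
#' @param methods Subset of `"mcace"` (global LRT) and `"univariate"`
#'   (Bonferroni over per-outcome LRTs).
#' @return Tibble of grid cells with attached settings.
#' @export
experiment_grid <- function(n_subjects = 100, p_compliance = 0.3,
                            effect = c(0, 1.5), n_replicates = 100,
                            base_seed = 1L,
                            methods = c("mcace", "univariate")) {
  stopifnot(n_replicates >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  g <- tidyr::expand_grid(n_subjects = n_subjects, p_compliance = p_compliance,
                          effect = effect)
  attr(g, "n_replicates") <- n_replicates
  attr(g, "base_seed") <- as.integer(base_seed)
  attr(g, "methods") <- methods
  g
}

power_one_replicate <- function(n, pc, effect, seed, methods, alpha, control,
                                missingness = NULL) {
  scen <- default_scenario(n_subjects = n, p_compliance = pc, effect = effect,
                           terms = c("t", "t2", "D:t"), missingness = missingness)
  sim <- simulate_trial(scen, seed = seed)
  out <- list()
  if ("mcace" %in% methods) {
    res <- tryCatch({
      spec <- scen$spec
      spec0 <- spec_drop_terms(spec, "D:t")
      fit1 <- mcace_fit(sim$data, spec, control = control, vcov = "none")
      fit0 <- mcace_fit(sim$data, spec0, control = control, vcov = "none")
      lrt <- global_lrt(fit1, fit0, alpha = alpha)
      list(reject = lrt$reject, converged = fit1$converged && fit0$converged)
    }, error = function(e) list(reject = NA, converged = FALSE))
    out$mcace <- res
  }
  if ("univariate" %in% methods) {
    res <- tryCatch({
      tab <- univariate_cace_all(sim$data, terms = c("t", "t2", "D:t"),
                                 control = control, alpha = alpha)
      list(reject = attr(tab, "reject_any"), converged = all(tab$converged))
    }, error = function(e) list(reject = NA, converged = FALSE))
    out$univariate <- res
  }
  out
}

#' Replicated power / type-I error study
#'
#' For each grid cell, simulates trials under the default two-factor scenario
#' with the cell's sample size, compliance rate and effect, and applies the
#' requested tests: the MCACE global likelihood-ratio test of no treatment
#' effect on any factor at level `alpha`, and the univariate comparator with
#' per-outcome LRTs at level `alpha / K`.
#'
#' @param grid An [experiment_grid()].
#' @param alpha Family-wise level (default 0.05).
#' @param control [fit_control()] for the per-replicate fits.
#' @param missingness Optional missingness passed to the scenario.
#' @param progress Emit a message per cell.
#' @return Tibble of class `mcace_power`: per (cell, method) the rejection
#'   proportion among converged replicates, its binomial Monte-Carlo SE, and
#'   the convergence counts.
#' @export
run_power_study <- function(grid, alpha = 0.05,
                            control = fit_control(n_restarts = 1),
                            missingness = NULL, progress = FALSE) {
  n_rep <- attr(grid, "n_replicates")
  base_seed <- attr(grid, "base_seed")
  methods <- attr(grid, "methods")
  rows <- list()
  for (ci in seq_len(nrow(grid))) {
    cell <- grid[ci, ]
    if (progress) message("cell ", ci, "/", nrow(grid), ": n=", cell$n_subjects,
                          " pc=", cell$p_compliance, " effect=", cell$effect)
    rep_res <- purrr::map(seq_len(n_rep), function(i) {
      power_one_replicate(cell$n_subjects, cell$p_compliance, cell$effect,
                          seed = base_seed + i, methods = methods,
                          alpha = alpha, control = control,
                          missingness = missingness)
    })
    for (m in methods) {
      rej <- vapply(rep_res, function(r) as.logical(r[[m]]$reject), NA)
      conv <- vapply(rep_res, function(r) isTRUE(r[[m]]$converged), NA)
      ok <- conv & !is.na(rej)
      phat <- mean(rej[ok])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n_subjects = cell$n_subjects, p_compliance = cell$p_compliance,
        effect = cell$effect, method = m,
        n_replicates = n_rep, n_converged = sum(ok),
        reject_rate = phat,
        mc_se = sqrt(phat * (1 - phat) / sum(ok))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mcace_power", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "base_seed") <- base_seed
  out
}

#' Parameter recovery and calibration study
#'
#' Replicated simulate-and-refit under a scenario: per free parameter, the
#' mean estimate, bias with its Monte-Carlo SE, empirical SD of the
#' estimates, mean model-based SE, and 95% Wald coverage of the truth.
#'
#' @param scenario A [sim_scenario()].
#' @param n_replicates Number of replicates.
#' @param base_seed Base seed; replicate i uses `base_seed + i`.
#' @param control [fit_control()] for the fits.
#' @param conf_level Nominal CI level for the coverage column.
#' @param progress Emit progress messages.
#' @return Tibble of class `mcace_recovery` with one row per free parameter,
#'   plus attribute `n_converged`.
#' @export
run_recovery_study <- function(scenario, n_replicates = 200, base_seed = 1L,
                               control = fit_control(n_restarts = 1),
                               conf_level = 0.95, progress = FALSE) {
  spec <- scenario$spec
  truth <- par_pack(scenario$params, spec, "original")
  p <- length(truth)
  est <- se <- matrix(NA_real_, n_replicates, p,
                      dimnames = list(NULL, names(truth)))
  conv <- logical(n_replicates)
  for (i in seq_len(n_replicates)) {
    if (progress && i %% 25 == 0) message("replicate ", i, "/", n_replicates)
    res <- tryCatch({
      sim <- simulate_trial(scenario, seed = base_seed + i)
      fit <- mcace_fit(sim$data, spec, control = control)
      list(theta = fit$theta, se = sqrt(pmax(diag(fit$vcov), 0)),
           converged = fit$converged)
    }, error = function(e) NULL)
    if (is.null(res) || !res$converged) next
    est[i, ] <- res$theta
    se[i, ] <- res$se
    conv[i] <- TRUE
  }
  R <- sum(conv)
  if (R == 0) stop("no replicate converged")
  est <- est[conv, , drop = FALSE]
  se <- se[conv, , drop = FALSE]
  zq <- qnorm(1 - (1 - conf_level) / 2)
  cover <- abs(sweep(est, 2, truth)) <= zq * se
  out <- tibble::tibble(
    term = names(truth),
    truth = unname(truth),
    mean_estimate = colMeans(est),
    bias = colMeans(est) - unname(truth),
    mc_se = apply(est, 2, sd) / sqrt(R),
    empirical_sd = apply(est, 2, sd),
    mean_se = colMeans(se),
    coverage = colMeans(cover),
    se_sd_ratio = colMeans(se) / apply(est, 2, sd)
  )
  class(out) <- c("mcace_recovery", class(out))
  attr(out, "n_converged") <- R
  attr(out, "n_replicates") <- n_replicates
  out
}

#' Model-selection study over candidate factor counts
#'
#' Simulates from a scenario and fits each candidate loading structure,
#' recording which candidate attains the lowest AIC (ties by BIC, then by
#' fewer parameters).
#'
#' @param scenario Generating [sim_scenario()].
#' @param candidates Named list of [mcace_spec()] candidates.
#' @param n_replicates,base_seed Replication settings.
#' @param control [fit_control()].
#' @return Tibble: candidate, times selected first by AIC, selection rate.
#' @export
run_selection_study <- function(scenario, candidates, n_replicates = 50,
                                base_seed = 1L,
                                control = fit_control(n_restarts = 1)) {
  winners <- character(0)
  for (i in seq_len(n_replicates)) {
    sim <- simulate_trial(scenario, seed = base_seed + i)
    fits <- purrr::map(candidates, function(sp) {
      tryCatch(mcace_fit(sim$data, sp, control = control, vcov = "none"),
               error = function(e) NULL)
    })
    fits <- purrr::compact(fits)
    if (length(fits) < length(candidates)) next
    tab <- compare_models(fits)
    winners <- c(winners, tab$model[1L])
  }
  tibble::tibble(candidate = names(candidates)) |>
    dplyr::mutate(
      n_selected = vapply(.data$candidate, function(k) sum(winners == k), 1),
      selection_rate = .data$n_selected / length(winners)
    )
}
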