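# Trial simulator.
#
# Generates two-arm trials under the latent-factor MCACE model: latent
# compliance strata with logistic membership, both potential-outcome arrays
# drawn with independent noise (cross-world correlation never enters the
# observed-data likelihood), and MAR missingness applied to post-baseline
# visits. The generator closes the loop with the closed-form marginal
# moments, which the tests exploit.

#' Simulation scenario
#'
#' Bundles a model specification, true parameter values, and trial-level
#' settings into a reproducible generator configuration.
#'
#' @param spec An [mcace_spec()].
#' @param params True parameter values (`mcace_params`).
#' @param n_subjects Number of randomized subjects.
#' @param allocation Probability of assignment to the treated arm
#'   (`fixed_allocation = TRUE` instead assigns exactly
#'   `round(allocation * n)` subjects).
#' @param missingness `NULL` for complete data, or a 2 x J matrix of deletion
#'   probabilities (rows: control, treated arms; columns: post-baseline
#'   visits), or a function `f(arm, visit, y_baseline)` returning a deletion
#'   probability (MAR: it may use baseline outcomes only).
#' @param compliance_covariate Optional generator for one extra binary
#'   compliance covariate: a list `list(name =, prob =)`; the covariate is
#'   Bernoulli(prob) and must have a matching entry in `params$eta`.
#' @param fixed_allocation Use deterministic per-arm counts.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(spec, params, n_subjects = 200, allocation = 0.5,
                         missingness = NULL, compliance_covariate = NULL,
                         fixed_allocation = FALSE) {
  stopifnot(allocation > 0, allocation < 1, is_count(n_subjects))
  if (is.matrix(missingness)) {
    stopifnot(nrow(missingness) == 2L, ncol(missingness) == spec$J1 - 1L,
              all(missingness >= 0), all(missingness <= 1))
  }
  structure(
    list(spec = spec, params = params, n_subjects = n_subjects,
         allocation = allocation, missingness = missingness,
         compliance_covariate = compliance_covariate,
         fixed_allocation = fixed_allocation),
    class = "sim_scenario"
  )
}

#' Default two-factor scenario
#'
#' The shipped study conditions: six outcomes at visits t = 0, 1, 2 driven by
#' two latent factors with the confirmatory grouping {1,2,3,5} / {4,6}, unit
#' free loadings, random-intercept and residual variances 1, a random linear
#' slope per factor with variance 0.5, a zero baseline treatment contrast,
#' intercept-only compliance, and 1:1 allocation. Compliance is
#' self-selected, so the strata differ: compliers start higher
#' (outcome intercepts +1) and improve faster (latent trend 0.5 t - 0.1 t^2)
#' than never-takers (intercepts -1, trend 0.2 t - 0.05 t^2). Distinct
#' mixture components are also what makes the control-arm mixture regular —
#' with identical strata, compliance membership would carry no information.
#' `effect` is the complier treatment-by-time coefficient shared by both
#' factors (the power-study dial); its quadratic companion defaults to zero.
#'
#' @param n_subjects Sample size.
#' @param p_compliance Complier prevalence (intercept-only logistic model).
#' @param effect Complier `D:t` coefficient, common to both factors.
#' @param effect_quad Complier `D:t2` coefficient.
#' @param terms Level-2 fixed terms (determines the fitted/generated model;
#'   the power study uses `c("t", "t2", "D:t")`).
#' @param missingness As in [sim_scenario()]; default none.
#' @return A `sim_scenario`.
#' @export
default_scenario <- function(n_subjects = 200, p_compliance = 0.3,
                             effect = 1.5, effect_quad = 0,
                             terms = c("t", "t2", "D:t", "D:t2"),
                             missingness = NULL) {
  spec <- mcace_spec(
    K = 6, Q = 2,
    loading = loading_confirmatory(list(c(1, 2, 3, 5), c(4, 6)), K = 6),
    level2 = level2_terms(fixed = terms, random = "t", baseline_balance = TRUE)
  )
  params <- par_template(spec)
  params$Lambda[spec$loading$mask] <- 1
  params$lambda0[, "c"] <- 1
  params$lambda0[, "n"] <- -1
  params$xi[] <- 1
  params$tau2[] <- 1
  params$Sigma_v <- lapply(params$Sigma_v, function(S) diag(0.5, nrow(S)))
  trend <- list(c = c(t = 0.5, t2 = -0.1), n = c(t = 0.2, t2 = -0.05))
  for (q in 1:2) {
    for (m in c("c", "n")) {
      if ("t" %in% stratum_terms(spec, m)) params <- set_beta(params, m, q, "t", trend[[m]]["t"])
      if ("t2" %in% stratum_terms(spec, m)) params <- set_beta(params, m, q, "t2", trend[[m]]["t2"])
    }
    if ("D:t" %in% spec$terms_c) params <- set_beta(params, "c", q, "D:t", effect)
    if ("D:t2" %in% spec$terms_c) params <- set_beta(params, "c", q, "D:t2", effect_quad)
  }
  params$eta["(Intercept)"] <- qlogis(p_compliance)
  sim_scenario(spec, params, n_subjects = n_subjects, missingness = missingness)
}

#' Motivating-trial missingness profile
#'
#' Per-arm, per-visit deletion probabilities matching the motivating trial's
#' follow-up profile: 6.1% / 14.3% (control, months 3 and 6) and 24.4% /
#' 22.2% (treated).
#' @return 2 x 2 matrix (rows control/treated, columns visits 1 and 2).
#' @export
example_missingness <- function() {
  matrix(c(0.061, 0.143, 0.244, 0.222), nrow = 2, byrow = TRUE,
         dimnames = list(c("control", "treated"), c("visit1", "visit2")))
}

draw_stratum_arm <- function(n, params, spec, stratum, arm, Xs, Z) {
  J1 <- spec$J1; K <- spec$K; QJ <- spec$Q * J1
  G <- kronecker(params$Lambda, diag(J1))
  Sv <- sigma_v_full(params)
  r <- nrow(Sv)
  Xb <- as.numeric(Xs %*% params$beta[[stratum]])
  V <- if (r > 0 && any(Sv != 0)) {
    matrix(rnorm(n * r), n, r) %*% chol(Sv + diag(1e-12 * max(diag(Sv)), r))
  } else if (r > 0) {
    matrix(rnorm(n * r), n, r) * 0   # keep the RNG stream layout
  } else {
    matrix(0, n, 0)
  }
  E <- matrix(rnorm(n * QJ, sd = sqrt(spec$eps_var)), n, QJ)
  U <- matrix(Xb, n, QJ, byrow = TRUE) + (if (r > 0) V %*% t(Z) else 0) + E
  B <- matrix(rnorm(n * K), n, K) %*% diag(sqrt(params$xi[, stratum]), K)
  Emeas <- matrix(rnorm(n * K * J1), n, K * J1) %*%
    diag(rep(sqrt(params$tau2[, stratum]), each = J1), K * J1)
  mu0 <- rep(params$lambda0[, stratum], each = J1)
  Y <- matrix(mu0, n, K * J1, byrow = TRUE) + U %*% t(G) +
    B[, rep(seq_len(K), each = J1), drop = FALSE] + Emeas
  list(Y = Y, U = U, V = V, B = B)
}

#' Simulate a randomized trial with noncompliance
#'
#' Draws compliance covariates and strata, randomizes assignment, generates
#' both potential-outcome arrays from the latent-factor model, assembles the
#' observed data from the realized arm, and applies MAR missingness.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Integer seed; identical scenario and seed give a bit-identical
#'   trial.
#' @param apply_missingness Apply the scenario's missingness (default TRUE).
#' @return An object of class `mcace_sim`: `data` (long tibble), `covariates`
#'   (per-subject tibble), and `truth` (stratum labels, latent factors,
#'   random effects, both potential-outcome matrices).
#' @export
simulate_trial <- function(scenario, seed = 1L, apply_missingness = TRUE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  spec <- scenario$spec; params <- scenario$params
  if (any(params$xi < 0) || any(params$tau2 < 0) || spec$eps_var < 0) {
    stop("variance parameters must be non-negative")
  }
  set.seed(seed)
  n <- scenario$n_subjects
  W <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  cov_tbl <- tibble::tibble(id = seq_len(n))
  cc <- scenario$compliance_covariate
  if (!is.null(cc)) {
    x <- rbinom(n, 1, cc$prob)
    W <- cbind(W, x)
    colnames(W)[2] <- cc$name
    cov_tbl[[cc$name]] <- x
  }
  eta <- params$eta[match(colnames(W), names(params$eta))]
  if (anyNA(eta)) stop("params$eta lacks entries for: ",
                       paste(colnames(W)[is.na(eta)], collapse = ", "))
  pci <- compliance_prob(W, eta)
  Ci <- ifelse(runif(n) < pci, "c", "n")
  arm <- if (scenario$fixed_allocation) {
    n1 <- round(scenario$allocation * n)
    sample(rep(c(1L, 0L), c(n1, n - n1)))
  } else {
    rbinom(n, 1, scenario$allocation)
  }
  receipt1 <- as.integer(Ci == "c")  # D_i(1); D_i(0) = 0 always

  Xc1 <- build_designs(spec, arm = 1, receipt = 1, stratum = "c")$X
  Xc0 <- build_designs(spec, arm = 0, receipt = 0, stratum = "c")$X
  dn <- build_designs(spec, arm = 1, receipt = 0, stratum = "n")
  Xn <- dn$X; Z <- dn$Z

  KJ <- spec$K * spec$J1
  Y1 <- Y0 <- matrix(NA_real_, n, KJ)
  U1 <- U0 <- matrix(NA_real_, n, spec$Q * spec$J1)
  truth_extra <- list()
  for (m in c("c", "n")) {
    ix <- which(Ci == m)
    if (!length(ix)) next
    d1 <- draw_stratum_arm(length(ix), params, spec, m, 1,
                           if (m == "c") Xc1 else Xn, Z)
    d0 <- draw_stratum_arm(length(ix), params, spec, m, 0,
                           if (m == "c") Xc0 else Xn, Z)
    Y1[ix, ] <- d1$Y; Y0[ix, ] <- d0$Y
    U1[ix, ] <- d1$U; U0[ix, ] <- d0$U
  }
  Yobs <- ifelse(matrix(arm == 1L, n, KJ), Y1, Y0)

  out <- tidyr::expand_grid(id = seq_len(n), visit = seq_len(spec$J1) - 1L)
  out$time <- spec$times[out$visit + 1L]
  out$arm <- arm[out$id]
  out$receipt <- ifelse(out$arm == 1L, receipt1[out$id], 0L)
  for (k in seq_len(spec$K)) {
    out[[spec$outcome_names[k]]] <- Yobs[cbind(out$id, (k - 1L) * spec$J1 + out$visit + 1L)]
  }
  out <- dplyr::relocate(out, "id", "arm", "receipt", "visit", "time")

  if (apply_missingness && !is.null(scenario$missingness)) {
    out <- inject_missingness(out, scenario$missingness,
                              outcome_cols = spec$outcome_names)
  }
  structure(
    list(data = out, covariates = cov_tbl,
         truth = list(stratum = Ci, receipt1 = receipt1, arm = arm,
                      U1 = U1, U0 = U0, Y1 = Y1, Y0 = Y0, p_complier = pci),
         scenario = scenario, seed = seed),
    class = "mcace_sim"
  )
}

#' @export
print.mcace_sim <- function(x, ...) {
  cat("<mcace_sim>", x$scenario$n_subjects, "subjects, seed", x$seed, "\n")
  cat("  compliers:", sum(x$truth$stratum == "c"), " treated:", sum(x$truth$arm == 1), "\n")
  invisible(x)
}

#' Delete post-baseline outcomes missing-at-random
#'
#' Deletes whole post-baseline visits with probabilities that depend only on
#' arm, visit, and (optionally) observed baseline outcomes — MAR by
#' construction. Baseline is never touched.
#'
#' @param data Long trial tibble (or an `mcace_sim`, whose `$data` is
#'   modified).
#' @param rates 2 x J matrix (rows control/treated, columns post-baseline
#'   visits) of deletion probabilities, or a function
#'   `f(arm, visit, y_baseline)` returning one probability per subject.
#' @param seed Optional seed (the caller's RNG stream is used when `NULL`).
#' @param outcome_cols Outcome column names (default: non-reserved columns).
#' @return Object of the same type as `data`.
#' @export
inject_missingness <- function(data, rates, seed = NULL, outcome_cols = NULL) {
  if (inherits(data, "mcace_sim")) {
    data$data <- inject_missingness(data$data, rates, seed,
                                    outcome_cols %||% data$scenario$spec$outcome_names)
    return(data)
  }
  if (!is.null(seed)) set.seed(seed)
  df <- data
  reserved <- c("id", "arm", "receipt", "visit", "time")
  outcome_cols <- outcome_cols %||% setdiff(names(df), reserved)
  visits <- sort(unique(df$visit))
  post <- visits[visits > 0]
  if (is.matrix(rates) && ncol(rates) != length(post)) {
    stop("rates must have one column per post-baseline visit")
  }
  base_rows <- df$visit == 0
  ybase <- df[base_rows, c("id", outcome_cols)]
  for (jj in seq_along(post)) {
    j <- post[jj]
    rows <- which(df$visit == j)
    sub <- df[rows, ]
    pr <- if (is.function(rates)) {
      yb <- ybase[match(sub$id, ybase$id), outcome_cols, drop = FALSE]
      vapply(seq_len(nrow(sub)), function(i) rates(sub$arm[i], j, as.numeric(yb[i, ])), 1)
    } else {
      rates[sub$arm + 1L, jj]
    }
    if (any(pr < 0 | pr > 1)) stop("deletion probabilities must lie in [0, 1]")
    del <- runif(nrow(sub)) < pr
    for (k in outcome_cols) df[rows[del], k] <- NA_real_
  }
  df
}

#' Threshold a simulated usage count into alternative compliance definitions
#'
#' Emulates sensitivity analyses that redefine the complier stratum from an
#' observed usage count (e.g. at least 6, 3 or 1 uses over six months):
#' treated-arm receipt is recoded as `usage >= threshold`.
#'
#' @param data Long trial tibble with a per-subject `usage` column (or a
#'   separate `usage` vector aligned with subject ids).
#' @param threshold Minimum usage defining compliance.
#' @param usage Optional per-subject usage counts named by id.
#' @return The data with `receipt` recoded (control arm untouched).
#' @export
redefine_compliance <- function(data, threshold, usage = NULL) {
  df <- data
  if (is.null(usage)) {
    if (!"usage" %in% names(df)) stop("provide a `usage` column or vector")
    u <- tapply(df$usage, df$id, function(x) x[1L])
  } else {
    u <- usage
  }
  comply <- as.integer(u[as.character(df$id)] >= threshold)
  df$receipt <- ifelse(df$arm == 1L, comply, 0L)
  df
}
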