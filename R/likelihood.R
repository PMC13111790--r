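# Observed-data likelihood.
#
# Subjects fall into three observed (arm, receipt) patterns: treated
# compliers (S11), treated never-takers (S10), and controls (S00), the last a
# mixture of compliers and never-takers weighted by the logistic compliance
# probability. Each contribution is a multivariate-normal density of the
# observed sub-vector (missing entries marginalized out analytically under
# MAR), and the control-arm mixture is combined in log space.

#' Log-density of the observed sub-vector of a multivariate normal
#'
#' Restricts `(mu, sigma)` to `obs_idx` and evaluates the Gaussian log-density
#' via a Cholesky factorization (no explicit inverse). Under MAR, this is the
#' correct marginal likelihood contribution of a partially observed vector.
#'
#' @param y_obs Observed values (length `length(obs_idx)`).
#' @param mu,sigma Moments of the full stacked vector.
#' @param obs_idx Integer indices of the observed entries.
#' @return Scalar log-density.
#' @export
dmvnorm_obs <- function(y_obs, mu, sigma, obs_idx = seq_along(mu)) {
  d <- length(obs_idx)
  stopifnot(length(y_obs) == d)
  S <- sigma[obs_idx, obs_idx, drop = FALSE]
  R <- chol_safe(S)
  w <- backsolve(R, y_obs - mu[obs_idx], transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(w^2)
}

#' Compliance probability under the logistic model
#'
#' Numerically stable evaluation of `plogis(W %*% eta)`.
#'
#' @param W Covariate matrix (rows are subjects; includes intercept column)
#'   or a single covariate vector.
#' @param eta Coefficient vector.
#' @return Probabilities in (0, 1).
#' @export
compliance_prob <- function(W, eta) {
  if (is.null(dim(W))) W <- matrix(W, nrow = 1)
  plogis(as.numeric(W %*% eta))
}

# Likelihood context: designs, stacked data, and subjects bucketed by
# (observed pattern, missing pattern) so Cholesky factors are shared.
make_context <- function(data, spec) {
  d <- as_mcace_data(data, spec = spec)
  if (!isTRUE(all.equal(d$times, spec$times))) {
    stop("data visit times do not match the spec schedule")
  }
  Xc1 <- build_designs(spec, arm = 1, receipt = 1, stratum = "c")$X
  Xc0 <- build_designs(spec, arm = 0, receipt = 0, stratum = "c")$X
  dn <- build_designs(spec, arm = 1, receipt = 0, stratum = "n")
  Xn <- dn$X; Z <- dn$Z
  lay <- par_layout(spec)
  W <- d$W[, spec$compliance_covariates, drop = FALSE]

  grp <- subject_group(d)
  obs <- !is.na(d$Y)
  pat_key <- apply(obs, 1L, function(r) paste(which(r), collapse = ","))
  key <- paste(grp, pat_key, sep = "|")
  buckets <- lapply(split(seq_len(d$N), key), function(ix) {
    o <- which(obs[ix[1L], ])
    list(
      type = c(S11 = 0L, S10 = 1L, S00 = 2L)[[grp[ix[1L]]]],
      obs = o - 1L,
      Y = t(d$Y[ix, o, drop = FALSE]),
      W = W[ix, , drop = FALSE],
      subjects = ix
    )
  })
  list(
    K = spec$K, J1 = spec$J1, Q = spec$Q, pw = ncol(W),
    sizes = as.integer(lay$sizes), offsets = as.integer(lay$offsets),
    loadk = lay$mask_idx[, 1] - 1L, loadq = lay$mask_idx[, 2] - 1L,
    rq = as.integer(lay$rq), Lfixed = spec$loading$fixed,
    Xc1 = Xc1, Xc0 = Xc0, Xn = Xn, Z = Z, eps_var = spec$eps_var,
    buckets = unname(buckets), N = d$N, layout = lay, data = d
  )
}

loglik_theta <- function(theta, ctx, transformed = TRUE) {
  cpp_mcace_loglik(theta, ctx, transformed)
}

#' Observed-data log-likelihood
#'
#' Sums, over subjects, the treated complier and never-taker Gaussian
#' contributions and the control-arm mixture, each on the subject's observed
#' entries.
#'
#' @param params An `mcace_params` list (original scale).
#' @param data Trial data (long tibble or `mcace_data`).
#' @param spec An [mcace_spec()].
#' @param covariates Optional covariate table when `data` is a long tibble.
#' @param engine `"cpp"` (compiled, default) or `"r"` (plain-R reference).
#' @return Scalar log-likelihood.
#' @export
loglik_mcace <- function(params, data, spec, covariates = NULL,
                         engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  d <- as_mcace_data(data, covariates, spec = spec)
  if (engine == "cpp") {
    ctx <- make_context(d, spec)
    theta <- par_pack(params, spec, "original")
    cpp_mcace_loglik(theta, ctx, FALSE)
  } else {
    loglik_mcace_r(params, d, spec)
  }
}

# Plain-R reference implementation (same math, subject-by-subject loops);
# used to cross-check the compiled engine and for subject-varying designs.
loglik_mcace_r <- function(params, data, spec) {
  d <- as_mcace_data(data, spec = spec)
  mom <- list(
    c1 = marginal_mu(params, spec, "c", arm = 1),
    c0 = marginal_mu(params, spec, "c", arm = 0),
    n  = marginal_mu(params, spec, "n", arm = 1)
  )
  Sig <- list(c = marginal_sigma(params, spec, "c"),
              n = marginal_sigma(params, spec, "n"))
  W <- d$W[, spec$compliance_covariates, drop = FALSE]
  lp <- as.numeric(W %*% params$eta)
  logp <- plogis(lp, log.p = TRUE)
  log1mp <- plogis(-lp, log.p = TRUE)
  grp <- subject_group(d)
  total <- 0
  for (i in seq_len(d$N)) {
    o <- which(!is.na(d$Y[i, ]))
    y <- d$Y[i, o]
    li <- tryCatch({
      if (grp[i] == "S11") {
        logp[i] + dmvnorm_obs(y, mom$c1, Sig$c, o)
      } else if (grp[i] == "S10") {
        log1mp[i] + dmvnorm_obs(y, mom$n, Sig$n, o)
      } else {
        a <- logp[i] + dmvnorm_obs(y, mom$c0, Sig$c, o)
        b <- log1mp[i] + dmvnorm_obs(y, mom$n, Sig$n, o)
        log_sum_exp(a, b)
      }
    }, error = function(e) {
      stop("likelihood evaluation failed for subject ", d$id[i], ": ",
           conditionMessage(e), call. = FALSE)
    })
    total <- total + li
  }
  total
}

#' Posterior probability of complier membership
#'
#' For control-arm subjects, the Bayes ratio of the complier mixture
#' component to the total; treated compliers return 1 and treated
#' never-takers 0 (their stratum is observed).
#'
#' @param params An `mcace_params` list, or an [mcace_fit()] object (in which
#'   case `data`/`spec` default to the fit's).
#' @param data Trial data.
#' @param spec An [mcace_spec()].
#' @return Tibble with `id`, `group`, `prob_complier`.
#' @export
posterior_compliance <- function(params, data = NULL, spec = NULL) {
  if (inherits(params, "mcace_fit")) {
    spec <- spec %||% params$spec
    data <- data %||% params$data
    params <- params$params
  }
  d <- as_mcace_data(data, spec = spec)
  mom_c0 <- marginal_mu(params, spec, "c", arm = 0)
  mom_n <- marginal_mu(params, spec, "n", arm = 0)
  Sig_c <- marginal_sigma(params, spec, "c")
  Sig_n <- marginal_sigma(params, spec, "n")
  W <- d$W[, spec$compliance_covariates, drop = FALSE]
  pci <- compliance_prob(W, params$eta)
  grp <- subject_group(d)
  prob <- numeric(d$N)
  for (i in seq_len(d$N)) {
    if (grp[i] == "S11") { prob[i] <- 1; next }
    if (grp[i] == "S10") { prob[i] <- 0; next }
    o <- which(!is.na(d$Y[i, ]))
    y <- d$Y[i, o]
    a <- log(pci[i]) + dmvnorm_obs(y, mom_c0, Sig_c, o)
    b <- log1p(-pci[i]) + dmvnorm_obs(y, mom_n, Sig_n, o)
    prob[i] <- exp(a - log_sum_exp(a, b))
  }
  tibble::tibble(id = d$id, group = grp, prob_complier = prob)
}
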