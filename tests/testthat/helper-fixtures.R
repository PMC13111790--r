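# Shared fixtures: small specs, parameter sets, and independent oracles.

# Quadratic six-outcome specification:, two factors with the confirmatory
# grouping {1,2,3,5} / {4,6}, quadratic time trends, zero baseline treatment
# contrast, random slopes on factor 1 only.
sixoutcome_spec <- function() {
  mcace_spec(
    K = 6, Q = 2,
    loading = loading_confirmatory(list(c(1, 2, 3, 5), c(4, 6)), K = 6),
    level2 = level2_terms(fixed = c("t", "t2", "D", "D:t", "D:t2"),
                          random = list(c("t", "t2"), character(0)),
                          baseline_balance = TRUE)
  )
}

# Two outcomes, one factor, two visits; every variance component active.
toy_spec <- function() {
  mcace_spec(
    K = 2, Q = 1, times = c(0, 1),
    loading = loading_confirmatory(list(c(1, 2)), K = 2),
    level2 = level2_terms(fixed = c("t", "D:t"), random = "t",
                          baseline_balance = TRUE)
  )
}

toy_params <- function(spec = toy_spec()) {
  p <- par_template(spec)
  p$Lambda[1, 1] <- 1.2
  p$Lambda[2, 1] <- 0.8
  p$lambda0[, "c"] <- c(1, -0.5)
  p$lambda0[, "n"] <- c(0.6, 0.2)
  p$xi[] <- c(0.6, 0.9, 0.5, 0.7)
  p$tau2[] <- c(0.8, 1.1, 0.9, 1.2)
  p$Sigma_v[[1]] <- matrix(0.4, 1, 1)
  p <- set_beta(p, "c", 1, "t", 0.3)
  p <- set_beta(p, "c", 1, "D:t", 1.0)
  p <- set_beta(p, "n", 1, "t", 0.3)
  p$eta["(Intercept)"] <- qlogis(0.4)
  p
}

# Generic dense parameter values for an arbitrary spec (seeded).
random_params <- function(spec, seed = 1) {
  set.seed(seed)
  p <- par_template(spec)
  p$lambda0[] <- rnorm(length(p$lambda0))
  p$Lambda[spec$loading$mask] <- runif(sum(spec$loading$mask), 0.5, 1.5)
  p$beta$c[] <- rnorm(length(p$beta$c), 0, 0.5)
  p$beta$n[] <- rnorm(length(p$beta$n), 0, 0.5)
  p$xi[] <- runif(length(p$xi), 0.3, 1.2)
  p$tau2[] <- runif(length(p$tau2), 0.5, 1.5)
  p$Sigma_v <- lapply(p$Sigma_v, function(S) {
    if (!length(S)) return(S)
    A <- matrix(rnorm(nrow(S)^2, 0, 0.4), nrow(S))
    crossprod(A) + diag(0.2, nrow(S))
  })
  p$eta[] <- rnorm(length(p$eta), 0, 0.5)
  p
}

# Independent scalar-loop evaluation of the marginal mean:
# mu[j,k] = lambda_m0k + sum_q lambda_kq * x_qj' beta_qm.
mu_scalar_oracle <- function(params, spec, stratum, arm) {
  receipt <- if (stratum == "c" && arm == 1) 1 else 0
  terms <- if (stratum == "c") spec$terms_c else spec$terms_n
  J1 <- spec$J1
  mu <- numeric(spec$K * J1)
  for (k in seq_len(spec$K)) {
    for (j in seq_len(J1)) {
      val <- params$lambda0[k, stratum]
      for (q in seq_len(spec$Q)) {
        xb <- 0
        for (tm in seq_along(terms)) {
          x <- mcace:::eval_term(terms[tm], spec$times[j], receipt)
          b <- params$beta[[stratum]][paste0("beta[", stratum, ",", q, ",", terms[tm], "]")]
          xb <- xb + x * b
        }
        val <- val + params$Lambda[k, q] * xb
      }
      mu[(k - 1) * J1 + j] <- val
    }
  }
  mu
}

# Independent scalar-loop covariance:
# Cov(y_jk, y_j'k') = sum_q sum_r l_kq l_k'r Cov(U_qj, U_rj')
#                   + [k == k'] xi_mk + [k == k', j == j'] tau2_mk,
# with Cov(U_qj, U_rj') = z_qj' Sigma_v[q,r] z_rj' + [q == r, j == j'] eps_var.
sigma_scalar_oracle <- function(params, spec, stratum) {
  J1 <- spec$J1; K <- spec$K; Q <- spec$Q
  rq <- vapply(spec$random, length, 1L)
  roff <- c(0, cumsum(rq))
  Sv <- mcace:::sigma_v_full(params)
  zvec <- function(q, j) {
    r <- spec$random[[q]]
    if (!length(r)) return(numeric(0))
    vapply(r, function(tm) mcace:::eval_term(tm, spec$times[j], 0), 1)
  }
  covU <- function(q, j, r, jp) {
    z1 <- zvec(q, j); z2 <- zvec(r, jp)
    out <- 0
    if (length(z1) && length(z2)) {
      blk <- Sv[(roff[q] + 1):roff[q + 1], (roff[r] + 1):roff[r + 1], drop = FALSE]
      out <- out + as.numeric(t(z1) %*% blk %*% z2)
    }
    if (q == r && j == jp) out <- out + spec$eps_var
    out
  }
  S <- matrix(0, K * J1, K * J1)
  for (k in seq_len(K)) for (j in seq_len(J1)) for (kp in seq_len(K)) for (jp in seq_len(J1)) {
    val <- 0
    for (q in seq_len(Q)) for (r in seq_len(Q)) {
      val <- val + params$Lambda[k, q] * params$Lambda[kp, r] * covU(q, j, r, jp)
    }
    if (k == kp) val <- val + params$xi[k, stratum]
    if (k == kp && j == jp) val <- val + params$tau2[k, stratum]
    S[(k - 1) * J1 + j, (kp - 1) * J1 + jp] <- val
  }
  S
}

# Full multivariate-normal log-density from first principles (chol).
log_mvn <- function(y, mu, S) {
  R <- chol(S)
  w <- backsolve(R, y - mu, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(w^2)
}

# Monte-Carlo estimate (and SE) of one component density f(y | stratum, arm)
# by integrating the hierarchical model over (v, eps, b) with measurement
# noise left analytic. Returns the density estimates for several y rows at
# once, sharing the draws.
mc_component_density <- function(Y, params, spec, stratum, arm, n_draws = 1e6,
                                 seed = 1) {
  set.seed(seed)
  receipt <- if (stratum == "c" && arm == 1) 1 else 0
  des <- build_designs(spec, arm = arm, receipt = receipt, stratum = stratum)
  J1 <- spec$J1; K <- spec$K; QJ <- spec$Q * J1
  G <- kronecker(params$Lambda, diag(J1))
  Sv <- mcace:::sigma_v_full(params)
  r <- nrow(Sv)
  Xb <- as.numeric(des$X %*% params$beta[[stratum]])
  V <- if (r > 0) matrix(rnorm(n_draws * r), n_draws, r) %*% chol(Sv) else matrix(0, n_draws, 0)
  E <- matrix(rnorm(n_draws * QJ, sd = sqrt(spec$eps_var)), n_draws, QJ)
  U <- matrix(Xb, n_draws, QJ, byrow = TRUE) + (if (r > 0) V %*% t(des$Z) else 0) + E
  B <- matrix(rnorm(n_draws * K), n_draws, K) %*% diag(sqrt(params$xi[, stratum]), K)
  M <- matrix(rep(params$lambda0[, stratum], each = J1), n_draws, K * J1, byrow = TRUE) +
    U %*% t(G) + B[, rep(seq_len(K), each = J1), drop = FALSE]
  sds <- rep(sqrt(params$tau2[, stratum]), each = J1)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  out <- t(apply(Y, 1, function(y) {
    ld <- rep(0, n_draws)
    for (c in seq_len(ncol(M))) ld <- ld + dnorm(y[c], M[, c], sds[c], log = TRUE)
    dens <- exp(ld)
    c(mean = mean(dens), se = sd(dens) / sqrt(n_draws))
  }))
  out
}

# A small deterministic trial with subjects in all three observed groups.
toy_trial <- function(n = 9, seed = 5, spec = toy_spec(), params = toy_params(spec)) {
  scen <- sim_scenario(spec, params, n_subjects = n)
  simulate_trial(scen, seed = seed)
}
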