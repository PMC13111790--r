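# Observed-data likelihood: densities, mixture, MAR marginalization, engines.

test_that("univariate standard-normal mode has the textbook log-density", {
  expect_equal(dmvnorm_obs(0, mu = 0, sigma = matrix(1, 1, 1)),
               log(1 / sqrt(2 * pi)))
})

test_that("full observation equals the unrestricted density", {
  spec <- toy_spec()
  p <- toy_params(spec)
  mu <- marginal_mu(p, spec, "c", 1)
  S <- marginal_sigma(p, spec, "c")
  set.seed(4)
  y <- mu + rnorm(length(mu))
  expect_equal(dmvnorm_obs(y, mu, S, seq_along(mu)), log_mvn(y, mu, S))
})

test_that("observed-subvector density equals grid marginalization over the missing block", {
  spec <- sixoutcome_spec()
  p <- random_params(spec, seed = 11)
  mu <- marginal_mu(p, spec, "c", 1)
  S <- marginal_sigma(p, spec, "c")          # 18-dimensional
  set.seed(21)
  y <- as.numeric(mu + t(chol(S)) %*% rnorm(length(mu)))
  mis <- c(5L, 12L)                           # two missing coordinates
  obs <- setdiff(seq_along(mu), mis)
  target <- dmvnorm_obs(y[obs], mu, S, obs)
  # trapezoid grid over the missing block, +- 8 marginal SDs
  sd1 <- sqrt(S[mis[1], mis[1]]); sd2 <- sqrt(S[mis[2], mis[2]])
  g1 <- seq(mu[mis[1]] - 8 * sd1, mu[mis[1]] + 8 * sd1, length.out = 241)
  g2 <- seq(mu[mis[2]] - 8 * sd2, mu[mis[2]] + 8 * sd2, length.out = 241)
  grid <- as.matrix(expand.grid(g1, g2))
  R <- chol(S)
  Ymat <- matrix(y, nrow(grid), length(y), byrow = TRUE)
  Ymat[, mis] <- grid
  Wm <- backsolve(R, t(Ymat) - mu, transpose = TRUE)
  logd <- -0.5 * length(y) * log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(Wm^2)
  integral <- sum(exp(logd)) * diff(g1)[1] * diff(g2)[1]
  expect_equal(exp(target), integral, tolerance = 1e-6)
})

test_that("compliance probabilities are correct and overflow-safe", {
  expect_equal(compliance_prob(1, 0), 0.5)
  expect_equal(compliance_prob(1, qlogis(0.3)), 0.3)
  expect_lte(compliance_prob(1, 40), 1)
  # the likelihood computes log(1 - p) stably: for a treated never-taker the
  # contribution shifts by exactly -10 when the linear predictor moves 40 -> 50
  spec <- toy_spec()
  p <- toy_params(spec)
  sim <- toy_trial(n = 20, seed = 6)
  df <- sim$data[sim$data$arm == 1, ]
  df$receipt <- 0              # all treated never-takers (S10 only)
  d <- mcace_data(df)
  p40 <- p; p40$eta["(Intercept)"] <- 40
  p50 <- p; p50$eta["(Intercept)"] <- 50
  ll40 <- loglik_mcace(p40, d, spec)
  ll50 <- loglik_mcace(p50, d, spec)
  expect_true(is.finite(ll40) && is.finite(ll50))
  expect_equal(ll40 - ll50, 10 * d$N, tolerance = 1e-6)
})

test_that("compiled and reference engines agree, with and without missingness", {
  scen <- default_scenario(n_subjects = 80, missingness = example_missingness())
  sim <- simulate_trial(scen, seed = 9)
  d <- mcace_data(sim$data)
  p0 <- initial_values(d, scen$spec)
  expect_equal(loglik_mcace(p0, d, scen$spec, engine = "cpp"),
               loglik_mcace(p0, d, scen$spec, engine = "r"), tolerance = 1e-10)
  expect_equal(loglik_mcace(scen$params, d, scen$spec, engine = "cpp"),
               loglik_mcace(scen$params, d, scen$spec, engine = "r"), tolerance = 1e-10)
})

test_that("analytic gradient matches central finite differences", {
  scen <- default_scenario(n_subjects = 60, missingness = example_missingness())
  sim <- simulate_trial(scen, seed = 13)
  d <- mcace_data(sim$data)
  ctx <- mcace:::make_context(d, scen$spec)
  for (transformed in c(TRUE, FALSE)) {
    th <- par_pack(scen$params, scen$spec, if (transformed) "transformed" else "original")
    ga <- mcace:::cpp_mcace_grad(th, ctx, transformed)
    gn <- mcace:::cpp_mcace_grad_fd(th, ctx, transformed)
    expect_lt(max(abs(ga - gn) / (1 + abs(gn))), 1e-4)
  }
})

test_that("degenerate mixture with certain compliance reduces to one stratum", {
  spec <- toy_spec()
  p <- toy_params(spec)
  p$eta["(Intercept)"] <- 500    # p_ci -> 1
  sim <- toy_trial(n = 12, seed = 8)
  d <- mcace_data(sim$data)
  d$receipt[d$arm == 1L] <- 1L   # coherent S11-only treated arm
  ll <- loglik_mcace(p, d, spec)
  # direct single-stratum evaluation: every subject a complier
  mu1 <- marginal_mu(p, spec, "c", 1); mu0 <- marginal_mu(p, spec, "c", 0)
  S <- marginal_sigma(p, spec, "c")
  direct <- sum(vapply(seq_len(d$N), function(i) {
    log_mvn(d$Y[i, ], if (d$arm[i] == 1) mu1 else mu0, S)
  }, 1))
  expect_equal(ll, direct, tolerance = 1e-8)
})

test_that("duplicating every subject exactly doubles the log-likelihood", {
  sim <- toy_trial(n = 10, seed = 3)
  spec <- toy_spec(); p <- toy_params(spec)
  df <- sim$data
  df2 <- rbind(df, transform(df, id = id + 1000))
  expect_equal(loglik_mcace(p, mcace_data(df2), spec),
               2 * loglik_mcace(p, mcace_data(df), spec), tolerance = 1e-10)
})

test_that("likelihood is invariant to subject order and coherent outcome permutation", {
  scen <- default_scenario(n_subjects = 40)
  sim <- simulate_trial(scen, seed = 17)
  spec <- scen$spec; p <- scen$params
  df <- sim$data
  ll <- loglik_mcace(p, mcace_data(df), spec)
  # subject order
  df_shuf <- df[order(rev(seq_len(nrow(df)))), ]
  expect_equal(loglik_mcace(p, mcace_data(df_shuf), spec), ll, tolerance = 1e-10)
  # permute outcome columns together with the loading rows, intercepts, variances
  perm <- c(3, 1, 2, 6, 4, 5)
  df_p <- df
  df_p[paste0("y", 1:6)] <- df[paste0("y", perm)]
  p_p <- p
  p_p$Lambda <- p$Lambda[perm, ]
  p_p$lambda0 <- p$lambda0[perm, ]
  p_p$xi <- p$xi[perm, ]
  p_p$tau2 <- p$tau2[perm, ]
  spec_p <- mcace_spec(K = 6, Q = 2, times = spec$times,
                       loading = loading_mask(spec$loading$mask[perm, ],
                                              spec$loading$fixed[perm, ]),
                       level2 = spec$level2)
  expect_equal(loglik_mcace(p_p, mcace_data(df_p), spec_p), ll, tolerance = 1e-10)
})

test_that("control-arm mixture respects the log-sum-exp lower bound without overflow", {
  spec <- toy_spec()
  p <- toy_params(spec)
  sim <- toy_trial(n = 30, seed = 6)
  d <- mcace_data(sim$data)
  # push one component's density to an extreme magnitude via a huge mean shift
  p_far <- p
  p_far$lambda0[, "n"] <- 200
  ll <- loglik_mcace(p_far, d, spec)
  expect_true(is.finite(ll))
  # per-subject bound: log L00 >= log(max component) + log(min(p, 1-p))
  mu_c0 <- marginal_mu(p, spec, "c", 0); mu_n <- marginal_mu(p, spec, "n", 0)
  Sc <- marginal_sigma(p, spec, "c"); Sn <- marginal_sigma(p, spec, "n")
  pci <- compliance_prob(1, p$eta)
  ctrl <- which(mcace:::subject_group(d) == "S00")
  for (i in ctrl[1:min(5, length(ctrl))]) {
    a <- log(pci) + log_mvn(d$Y[i, ], mu_c0, Sc)
    b <- log(1 - pci) + log_mvn(d$Y[i, ], mu_n, Sn)
    mix <- mcace:::log_sum_exp(a, b)
    expect_gte(mix + 1e-10, max(a, b))
    expect_gte(mix + 1e-10, max(log_mvn(d$Y[i, ], mu_c0, Sc), log_mvn(d$Y[i, ], mu_n, Sn)) +
                 log(min(pci, 1 - pci)))
  }
})

test_that("deleting an entry marginalizes rather than distorts the likelihood", {
  spec <- toy_spec(); p <- toy_params(spec)
  sim <- toy_trial(n = 8, seed = 12)
  df <- sim$data
  # delete outcome y2 at the last visit for one control subject
  ctrl_ids <- unique(df$id[df$arm == 0])
  i <- ctrl_ids[1]
  df2 <- df
  df2$y2[df2$id == i & df2$visit == 1] <- NA
  d <- mcace_data(df)
  d2 <- mcace_data(df2)
  ll_diff <- loglik_mcace(p, d2, spec) - loglik_mcace(p, d, spec)
  # the restricted subject's contribution equals the analytic marginal
  mu_c0 <- marginal_mu(p, spec, "c", 0); mu_n <- marginal_mu(p, spec, "n", 0)
  Sc <- marginal_sigma(p, spec, "c"); Sn <- marginal_sigma(p, spec, "n")
  pci <- compliance_prob(1, p$eta)
  row <- which(d$id == i)
  y <- d$Y[row, ]
  o <- setdiff(seq_along(y), 4L)  # y2 at visit 1 sits at stacked position 4
  full <- mcace:::log_sum_exp(log(pci) + dmvnorm_obs(y, mu_c0, Sc),
                              log(1 - pci) + dmvnorm_obs(y, mu_n, Sn))
  marg <- mcace:::log_sum_exp(log(pci) + dmvnorm_obs(y[o], mu_c0, Sc, o),
                              log(1 - pci) + dmvnorm_obs(y[o], mu_n, Sn, o))
  expect_equal(ll_diff, marg - full, tolerance = 1e-9)
})

test_that("posterior compliance is the Bayes ratio, with observed strata fixed", {
  spec <- toy_spec(); p <- toy_params(spec)
  sim <- toy_trial(n = 25, seed = 10)
  d <- mcace_data(sim$data)
  post <- posterior_compliance(p, d, spec)
  expect_equal(post$prob_complier[post$group == "S11"],
               rep(1, sum(post$group == "S11")))
  expect_equal(post$prob_complier[post$group == "S10"],
               rep(0, sum(post$group == "S10")))
  # hand-computed ratio for the first control subject
  i <- which(post$group == "S00")[1]
  mu_c0 <- marginal_mu(p, spec, "c", 0); mu_n <- marginal_mu(p, spec, "n", 0)
  Sc <- marginal_sigma(p, spec, "c"); Sn <- marginal_sigma(p, spec, "n")
  pci <- compliance_prob(1, p$eta)
  num <- pci * exp(log_mvn(d$Y[i, ], mu_c0, Sc))
  den <- num + (1 - pci) * exp(log_mvn(d$Y[i, ], mu_n, Sn))
  expect_equal(post$prob_complier[i], num / den, tolerance = 1e-10)
  # identical component densities return the prior probability
  p_same <- p
  p_same$lambda0[, "n"] <- p$lambda0[, "c"]
  p_same$xi[, "n"] <- p$xi[, "c"]
  p_same$tau2[, "n"] <- p$tau2[, "c"]
  p_same$beta$n[] <- 0
  p_same$beta$c[] <- 0
  post2 <- posterior_compliance(p_same, d, spec)
  expect_equal(post2$prob_complier[post2$group == "S00"],
               rep(compliance_prob(1, p$eta), sum(post2$group == "S00")),
               tolerance = 1e-10)
})

test_that("toy log-likelihood matches brute-force Monte-Carlo integration", {
  spec <- toy_spec()
  p <- toy_params(spec)
  sim <- toy_trial(n = 9, seed = 5)
  d <- mcace_data(sim$data)
  grp <- mcace:::subject_group(d)
  expect_setequal(unique(grp), c("S11", "S10", "S00"))
  pci <- compliance_prob(1, p$eta)
  n_draws <- 1e6
  dens_c1 <- mc_component_density(d$Y[grp == "S11", , drop = FALSE], p, spec, "c", 1,
                                  n_draws, seed = 101)
  dens_n <- mc_component_density(d$Y[grp != "S11", , drop = FALSE], p, spec, "n", 0,
                                 n_draws, seed = 102)
  dens_c0 <- mc_component_density(d$Y[grp == "S00", , drop = FALSE], p, spec, "c", 0,
                                  n_draws, seed = 103)
  ll_mc <- 0; se_sq <- 0
  idx_n <- which(grp != "S11")
  for (i in seq_len(d$N)) {
    if (grp[i] == "S11") {
      r <- dens_c1[which(which(grp == "S11") == i), ]
      f <- pci * r["mean"]; fse <- pci * r["se"]
    } else if (grp[i] == "S10") {
      r <- dens_n[which(idx_n == i), ]
      f <- (1 - pci) * r["mean"]; fse <- (1 - pci) * r["se"]
    } else {
      rc <- dens_c0[which(which(grp == "S00") == i), ]
      rn <- dens_n[which(idx_n == i), ]
      f <- pci * rc["mean"] + (1 - pci) * rn["mean"]
      fse <- sqrt((pci * rc["se"])^2 + ((1 - pci) * rn["se"])^2)
    }
    ll_mc <- ll_mc + log(f)
    se_sq <- se_sq + (fse / f)^2
  }
  ll <- loglik_mcace(p, d, spec)
  expect_lt(abs(ll - ll_mc), 3 * sqrt(se_sq) + 1e-8)
})
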