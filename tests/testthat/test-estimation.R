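# Maximum-likelihood fitting, starting values, observed information.

test_that("starting values match moments and reject degenerate outcomes", {
  scen <- default_scenario(n_subjects = 120, p_compliance = 0.3)
  sim <- simulate_trial(scen, seed = 19)
  d <- mcace_data(sim$data)
  p0 <- initial_values(d, scen$spec)
  pc_hat <- mean(d$receipt[d$arm == 1])
  expect_equal(unname(p0$eta["(Intercept)"]), qlogis(pc_hat))
  expect_true(all(p0$xi > 0) && all(p0$tau2 > 0))
  # anchors positive
  for (q in 1:2) {
    a <- scen$spec$loading$anchors[q]
    expect_gt(p0$Lambda[a, q], 0)
  }
  # degenerate outcome named in the error
  df <- sim$data
  df$y3 <- 5
  expect_error(initial_values(mcace_data(df), scen$spec), "y3")
})

test_that("log-likelihood is invariant under the pack/unpack transform", {
  scen <- default_scenario(n_subjects = 50)
  sim <- simulate_trial(scen, seed = 23)
  d <- mcace_data(sim$data)
  spec <- scen$spec
  for (seed in 1:2) {
    p <- random_params(spec, seed)
    ll0 <- loglik_mcace(p, d, spec)
    p_rt <- par_unpack(par_pack(p, spec, "transformed"), spec, "transformed")
    expect_equal(loglik_mcace(p_rt, d, spec), ll0, tolerance = 1e-8)
  }
})

test_that("refitting from the optimum reproduces the maximized log-likelihood", {
  scen <- default_scenario(n_subjects = 120)
  sim <- simulate_trial(scen, seed = 29)
  fit <- mcace_fit(sim$data, scen$spec, control = fit_control(n_restarts = 1),
                   vcov = "none")
  refit <- mcace_fit(sim$data, scen$spec, start = fit$params,
                     control = fit_control(n_restarts = 1), vcov = "none")
  expect_true(fit$converged)
  expect_equal(refit$loglik, fit$loglik, tolerance = 1e-8)
})

test_that("certain compliance collapses the fit to a single-stratum MVN model", {
  scen <- default_scenario(n_subjects = 200, p_compliance = 0.995)
  sim <- simulate_trial(scen, seed = 31)
  df <- sim$data
  df$receipt[df$arm == 1] <- 1   # a fully complying treated arm
  fit <- mcace_fit(df, scen$spec, control = fit_control(n_restarts = 1),
                   vcov = "none")
  # the fitted mixture weight approaches 1 and the complier block recovers the
  # single-stratum generating values (the never-taker block is then idle)
  pci <- compliance_prob(1, fit$params$eta)
  expect_gt(pci, 0.9)
  expect_lt(max(abs(fit$params$beta$c - scen$params$beta$c)), 0.5)
  expect_lt(max(abs(fit$params$lambda0[, "c"] - scen$params$lambda0[, "c"])), 0.6)
})

test_that("information criteria follow their definitions", {
  scen <- default_scenario(n_subjects = 80)
  sim <- simulate_trial(scen, seed = 37)
  fit <- mcace_fit(sim$data, scen$spec, control = fit_control(n_restarts = 1),
                   vcov = "none")
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_free)
  expect_equal(fit$bic, -2 * fit$loglik + log(fit$n_subjects) * fit$n_free)
  g <- glance(fit)
  expect_equal(g$AIC, fit$aic)
  expect_equal(g$nobs, 80)
})

test_that("finite-difference Hessian is exact for a quadratic function", {
  A <- matrix(c(2, 0.5, 0.3, 0.5, 1.5, 0.2, 0.3, 0.2, 1.0), 3, 3)
  fn <- function(x) -0.5 * drop(t(x) %*% A %*% x) + sum(x)
  H <- mcace:::fd_hessian(fn, c(0.3, -0.2, 0.8))
  expect_equal(H, -A, tolerance = 1e-5)
})

test_that("observed information matches the model-free Hessian and both scales agree", {
  scen <- default_scenario(n_subjects = 150)
  sim <- simulate_trial(scen, seed = 41)
  fit <- mcace_fit(sim$data, scen$spec, control = fit_control(n_restarts = 1),
                   vcov = "original-fd")
  d <- fit$data; spec <- fit$spec
  # cross-check a sub-block against the generic fd_hessian on the original scale
  ctx <- mcace:::make_context(d, spec)
  th <- par_pack(fit$params, spec, "original")
  idx <- 1:4
  fn <- function(x) { t2 <- th; t2[idx] <- x; mcace:::cpp_mcace_loglik(t2, ctx, FALSE) }
  Hsub <- mcace:::fd_hessian(fn, th[idx], step = 1e-4)
  Hfull <- mcace:::cpp_mcace_hessian(th, ctx, FALSE, 1e-4)
  expect_equal(Hsub, Hfull[idx, idx], tolerance = 1e-3)
  # delta-method route agrees with the original-scale route away from bounds
  oi_t <- observed_information(fit$params, d, spec, fit$control, scale = "transformed")
  se_o <- sqrt(diag(fit$vcov))
  se_t <- sqrt(diag(oi_t$vcov))
  expect_lt(max(abs(se_t - se_o) / se_o), 0.05)
})

test_that("variance estimates at the transform floor are flagged, not hidden", {
  scen <- default_scenario(n_subjects = 150)
  # remove the random-intercept signal so xi estimates crash into the boundary
  scen$params$xi[] <- 0
  sim <- simulate_trial(scen, seed = 43)
  fit <- mcace_fit(sim$data, scen$spec, control = fit_control(n_restarts = 1),
                   vcov = "none")
  expect_true(length(fit$boundary) > 0)
})

test_that("a large-sample single fit lands near the generating values", {
  scen <- default_scenario(n_subjects = 2000, p_compliance = 0.4)
  sim <- simulate_trial(scen, seed = 47)
  fit <- mcace_fit(sim$data, scen$spec, control = fit_control(n_restarts = 1),
                   vcov = "none")
  truth <- par_pack(scen$params, scen$spec, "original")
  est <- fit$theta
  expect_true(fit$converged)
  expect_lt(max(abs(est - truth)), 0.35)
  expect_lt(mean(abs(est - truth)), 0.08)
})
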