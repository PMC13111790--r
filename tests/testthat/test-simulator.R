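# Trial generator: determinism, consistency, compliance, missingness.

test_that("degenerate noise collapses outcomes to the measurement intercepts", {
  spec <- toy_spec()
  p <- toy_params(spec)
  p$xi[] <- 0; p$tau2[] <- 0
  p$Sigma_v[[1]] <- matrix(0, 1, 1)
  p$beta$c[] <- 0; p$beta$n[] <- 0
  spec0 <- spec; spec0$eps_var <- 0
  scen <- sim_scenario(spec0, p, n_subjects = 30)
  sim <- simulate_trial(scen, seed = 2)
  for (m in c("c", "n")) {
    ix <- sim$truth$stratum == m
    expect_equal(sim$truth$Y1[ix, ],
                 matrix(rep(p$lambda0[, m], each = spec$J1), sum(ix),
                        spec$K * spec$J1, byrow = TRUE),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("treated-arm compliance fraction matches the logistic model", {
  scen <- default_scenario(n_subjects = 20000, p_compliance = 0.3)
  sim <- simulate_trial(scen, seed = 71)
  treated <- sim$truth$arm == 1
  frac <- mean(sim$truth$receipt1[treated])
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / sum(treated)))
})

test_that("identical scenario and seed give bit-identical trials", {
  scen <- default_scenario(n_subjects = 60, missingness = example_missingness())
  s1 <- simulate_trial(scen, seed = 123)
  s2 <- simulate_trial(scen, seed = 123)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_trial(scen, seed = 124)
  expect_false(identical(s1$data, s3$data))
})

test_that("observed outcomes are the realized-arm potential outcomes", {
  scen <- default_scenario(n_subjects = 50)
  sim <- simulate_trial(scen, seed = 5, apply_missingness = FALSE)
  d <- mcace_data(sim$data)
  for (i in seq_len(d$N)) {
    expected <- if (sim$truth$arm[i] == 1) sim$truth$Y1[i, ] else sim$truth$Y0[i, ]
    expect_equal(unname(d$Y[i, ]), expected, tolerance = 1e-12)
  }
  # receipt consistency under no control access
  expect_true(all(d$receipt[d$arm == 0] == 0))
  treated <- d$arm == 1
  expect_equal(d$receipt[treated],
               as.integer(sim$truth$stratum[treated] == "c"))
})

test_that("MAR deletion hits the configured per-arm, per-visit rates", {
  rates <- matrix(c(0.061, 0.143, 0.244, 0.222), 2, byrow = TRUE)
  scen <- default_scenario(n_subjects = 10000)
  sim <- simulate_trial(scen, seed = 77, apply_missingness = FALSE)
  df <- inject_missingness(sim$data, rates, seed = 78)
  for (a in 0:1) for (j in 1:2) {
    sub <- df[df$arm == a & df$visit == j, ]
    fmiss <- mean(is.na(sub$y1))
    p <- rates[a + 1, j]
    expect_lt(abs(fmiss - p), 4 * sqrt(p * (1 - p) / nrow(sub)))
    # deletion is at the visit level: all outcomes jointly missing
    expect_equal(is.na(sub$y1), is.na(sub$y6))
  }
  # baseline untouched
  expect_false(anyNA(df[df$visit == 0, paste0("y", 1:6)]))
  # zero rates are the identity
  expect_identical(inject_missingness(sim$data, matrix(0, 2, 2), seed = 1),
                   sim$data)
})

test_that("baseline-dependent MAR rules produce the prescribed deletion gradient", {
  scen <- default_scenario(n_subjects = 20000)
  sim <- simulate_trial(scen, seed = 81, apply_missingness = FALSE)
  rule <- function(arm, visit, y_baseline) plogis(-2 + 0.8 * mean(y_baseline))
  df <- inject_missingness(sim$data, rule, seed = 82)
  base_mean <- tapply(rowMeans(sim$data[sim$data$visit == 0, paste0("y", 1:6)]),
                      sim$data$id[sim$data$visit == 0], identity)
  v1 <- df[df$visit == 1, ]
  bm <- base_mean[as.character(v1$id)]
  hi <- bm > stats::median(bm)
  p_hi <- mean(is.na(v1$y1[hi])); p_lo <- mean(is.na(v1$y1[!hi]))
  exp_hi <- mean(plogis(-2 + 0.8 * bm[hi])); exp_lo <- mean(plogis(-2 + 0.8 * bm[!hi]))
  expect_lt(abs(p_hi - exp_hi), 4 * sqrt(exp_hi * (1 - exp_hi) / sum(hi)))
  expect_lt(abs(p_lo - exp_lo), 4 * sqrt(exp_lo * (1 - exp_lo) / sum(!hi)))
  expect_gt(p_hi, p_lo)
})

test_that("randomization balances covariates across arms", {
  scen <- default_scenario(n_subjects = 5000)
  scen$compliance_covariate <- list(name = "w1", prob = 0.5)
  scen$params$eta <- c(scen$params$eta, w1 = 0.7)
  names(scen$params$eta)[1] <- "(Intercept)"
  sim <- simulate_trial(scen, seed = 91)
  w <- sim$covariates$w1
  arm <- sim$truth$arm
  diff <- abs(mean(w[arm == 1]) - mean(w[arm == 0]))
  expect_lt(diff, 4 * sqrt(0.25 * (1 / sum(arm == 1) + 1 / sum(arm == 0))))
})

test_that("compliance redefinition recodes receipt by usage threshold", {
  df <- tidyr::expand_grid(id = 1:6, visit = 0:2)
  df$arm <- rep(c(1, 1, 1, 0, 0, 0), each = 3)
  df$receipt <- 0
  df$y1 <- rnorm(nrow(df))
  usage <- setNames(c(7, 3, 0, 5, 1, 2), 1:6)
  out6 <- redefine_compliance(df, threshold = 6, usage = usage)
  expect_equal(unique(out6$receipt[out6$id == 1]), 1)
  expect_equal(unique(out6$receipt[out6$id == 2]), 0)
  out3 <- redefine_compliance(df, threshold = 3, usage = usage)
  expect_equal(unique(out3$receipt[out3$id == 2]), 1)
  # control arm never recoded
  expect_true(all(out3$receipt[out3$arm == 0] == 0))
})
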