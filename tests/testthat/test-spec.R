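# Model specification, design construction, parameter packing.

test_that("quadratic design rows evaluate the stated polynomial terms", {
  spec <- mcace_spec(
    K = 6, Q = 2,
    loading = loading_confirmatory(list(c(1, 2, 3, 5), c(4, 6)), K = 6),
    level2 = level2_terms(fixed = c("t", "t2", "D", "D:t", "D:t2"),
                          random = "t", baseline_balance = FALSE)
  )
  X <- build_designs(spec, times = c(0, 1, 2), arm = 1, receipt = 1, stratum = "c")$X
  # factor-1 rows, columns (t, t2, D, D:t, D:t2)
  expect_equal(unname(X[1:3, 1:5]),
               rbind(c(0, 0, 1, 0, 0), c(1, 1, 1, 1, 1), c(2, 4, 1, 2, 4)))
  # factor-major block structure: factor-1 rows have zero factor-2 columns
  expect_true(all(X[1:3, 6:10] == 0))
  expect_equal(unname(X[4:6, 6:10]), unname(X[1:3, 1:5]))
})

test_that("control-arm design zeroes exactly the treatment columns", {
  spec <- mcace_spec(
    K = 6, Q = 2,
    loading = loading_confirmatory(list(c(1, 2, 3, 5), c(4, 6)), K = 6),
    level2 = level2_terms(fixed = c("t", "t2", "D", "D:t", "D:t2"),
                          random = "t", baseline_balance = FALSE)
  )
  X1 <- build_designs(spec, arm = 1, receipt = 1, stratum = "c")$X
  X0 <- build_designs(spec, arm = 0, receipt = 0, stratum = "c")$X
  trt <- grepl("D", colnames(X1))
  expect_true(all(X0[, trt] == 0))
  expect_equal(X0[, !trt], X1[, !trt])
})

test_that("zero-constrained baseline contrast removes the D main-effect column", {
  spec <- default_scenario()$spec  # baseline_balance = TRUE
  X <- build_designs(spec, arm = 1, receipt = 1, stratum = "c")$X
  expect_false(any(grepl("\\bD\\]", colnames(X))))
  expect_true(any(grepl("D:t", colnames(X))))
  # never-takers carry no treatment columns at all
  Xn <- build_designs(spec, arm = 1, receipt = 0, stratum = "n")$X
  expect_false(any(grepl("D", colnames(Xn))))
})

test_that("validation accepts the study specifications and flags violations", {
  expect_equal(nrow(validate_spec(sixoutcome_spec())), 0L)
  expect_equal(nrow(validate_spec(default_scenario()$spec)), 0L)
  expect_equal(nrow(validate_spec(toy_spec())), 0L)

  # intercept in the structural model
  sp <- mcace_spec(K = 2, Q = 1,
                   loading = loading_confirmatory(list(1:2), K = 2),
                   level2 = level2_terms(fixed = c("1", "t"), random = character(0)))
  f <- validate_spec(sp)
  expect_true(any(f$severity == "error" & grepl("intercept", f$message)))

  # exploratory structure with a free loading above the diagonal
  mask <- matrix(TRUE, 2, 2)
  sp2 <- mcace_spec(K = 2, Q = 2,
                    loading = loading_mask(mask, mode = "exploratory"),
                    level2 = level2_terms(fixed = "t", random = character(0)))
  f2 <- validate_spec(sp2)
  expect_true(any(f2$severity == "error" & grepl("q > k", f2$message)))

  # random terms outside the fixed terms
  sp3 <- mcace_spec(K = 2, Q = 1,
                    loading = loading_confirmatory(list(1:2), K = 2),
                    level2 = level2_terms(fixed = "t", random = c("t", "t2")))
  f3 <- validate_spec(sp3)
  expect_true(any(f3$severity == "error" & grepl("subset", f3$message)))

  # too many factors
  sp4 <- mcace_spec(K = 2, Q = 2,
                    loading = loading_confirmatory(list(1, 2), K = 2),
                    level2 = level2_terms(fixed = "t", random = character(0)))
  f4 <- validate_spec(sp4)
  expect_true(any(f4$severity == "warning"))
})

test_that("exploratory masks fix loadings above the diagonal", {
  l <- loading_exploratory(K = 4, Q = 2)
  expect_false(l$mask[1, 2])
  expect_true(all(l$mask[2:4, 2]))
  expect_true(all(l$mask[, 1]))
})

test_that("unknown terms and misuse of receipt raise errors", {
  spec <- toy_spec()
  expect_error(build_designs(spec, arm = 0, receipt = 1, stratum = "c"), "control arm")
  expect_error(build_designs(spec, arm = 1, receipt = 1, stratum = "n"), "never-takers")
  sp <- mcace_spec(K = 2, Q = 1,
                   loading = loading_confirmatory(list(1:2), K = 2),
                   level2 = level2_terms(fixed = c("t", "bogus"), random = character(0)))
  expect_error(build_designs(sp, arm = 1, receipt = 1, stratum = "c"), "unknown level-2 term")
})

test_that("pack/unpack round trip is the identity on both scales", {
  for (spec in list(toy_spec(), sixoutcome_spec(), default_scenario()$spec)) {
    for (seed in 1:3) {
      p <- random_params(spec, seed = seed)
      for (scale in c("original", "transformed")) {
        th <- par_pack(p, spec, scale)
        th2 <- par_pack(par_unpack(th, spec, scale), spec, scale)
        expect_equal(th, th2, tolerance = 1e-9)
      }
      # params -> theta -> params preserves every component
      p2 <- par_unpack(par_pack(p, spec, "transformed"), spec, "transformed")
      expect_equal(p2$Lambda, p$Lambda, tolerance = 1e-9)
      expect_equal(p2$Sigma_v, p$Sigma_v, tolerance = 1e-7)
      expect_equal(p2$beta, p$beta, tolerance = 1e-12)
    }
  }
})

test_that("sign canonicalization flips a factor without changing the likelihood", {
  spec <- toy_spec()
  p <- toy_params(spec)
  pf <- p
  pf$Lambda[, 1] <- -pf$Lambda[, 1]
  pf$beta$c <- -pf$beta$c
  pf$beta$n <- -pf$beta$n
  sim <- toy_trial(n = 20)
  d <- mcace_data(sim$data)
  expect_equal(loglik_mcace(pf, d, spec), loglik_mcace(p, d, spec), tolerance = 1e-10)
  pc <- mcace:::canonicalize_signs(pf, spec)
  expect_equal(pc$Lambda, p$Lambda)
  expect_equal(pc$beta, p$beta)
})
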