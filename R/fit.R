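# Maximum-likelihood estimation.
#
# The log-likelihood is maximized by quasi-Newton (BFGS) iteration on an
# unconstrained transform of the parameters (log variances, log-Cholesky
# random-effect blocks), with analytic gradients from the compiled core.
# Standard errors come from the inverse observed information (negative
# Hessian), by default finite-differenced in the original parameterization;
# when a variance estimate sits near the boundary the transformed-scale
# Hessian with a delta-method back-transform is used instead.

#' Fitting options
#'
#' @param max_iter Maximum BFGS iterations.
#' @param rel_tol Relative log-likelihood convergence tolerance.
#' @param grad_tol Gradient-norm threshold used to report convergence.
#' @param n_restarts Number of optimizer starts (the first from
#'   [initial_values()], the rest jittered).
#' @param seed Seed for the restart jitter.
#' @param hessian_step Relative finite-difference step for the observed
#'   information.
#' @param boundary_tol Variances below this value are flagged as boundary
#'   estimates and switch the Hessian to the transformed scale.
#' @return A `fit_control` list.
#' @export
fit_control <- function(max_iter = 2000, rel_tol = 1e-9, grad_tol = 1e-5,
                        n_restarts = 3, seed = 1L, hessian_step = 1e-4,
                        boundary_tol = 1e-5) {
  stopifnot(rel_tol > 0, grad_tol > 0, n_restarts >= 1)
  list(max_iter = max_iter, rel_tol = rel_tol, grad_tol = grad_tol,
       n_restarts = n_restarts, seed = seed, hessian_step = hessian_step,
       boundary_tol = boundary_tol)
}

#' Moment-based starting values
#'
#' Deterministic given the seed: measurement intercepts from baseline outcome
#' means; random-intercept and residual variances from halves of the
#' within-subject variances; free loadings from baseline principal
#' components restricted to the mask (anchored positive); zero fixed effects;
#' small positive random-effect variances; compliance intercept at the logit
#' of the treated-arm compliance fraction.
#'
#' @param data Trial data.
#' @param spec An [mcace_spec()].
#' @param seed Unused by the deterministic recipe but kept in the signature
#'   for reproducibility contracts.
#' @return An `mcace_params` list.
#' @export
initial_values <- function(data, spec, seed = 1L) {
  d <- as_mcace_data(data, spec = spec)
  params <- par_template(spec)
  J1 <- spec$J1
  base_idx <- (seq_len(spec$K) - 1L) * J1 + 1L
  Yb <- d$Y[, base_idx, drop = FALSE]
  for (k in seq_len(spec$K)) {
    yk <- d$Y[, (k - 1L) * J1 + seq_len(J1), drop = FALSE]
    if (all(is.na(yk)) || stats::var(as.numeric(yk), na.rm = TRUE) < 1e-12) {
      stop("outcome '", spec$outcome_names[k], "' is degenerate (no variance)")
    }
  }
  params$lambda0[, "c"] <- params$lambda0[, "n"] <- colMeans(Yb, na.rm = TRUE)
  within_var <- vapply(seq_len(spec$K), function(k) {
    yk <- d$Y[, (k - 1L) * J1 + seq_len(J1), drop = FALSE]
    v <- apply(yk, 1L, function(r) if (sum(!is.na(r)) > 1L) stats::var(r, na.rm = TRUE) else NA_real_)
    mean(v, na.rm = TRUE)
  }, 1)
  within_var[!is.finite(within_var)] <- 1
  half <- pmax(within_var / 2, 0.05)
  params$xi[] <- half
  params$tau2[] <- half
  if (any(spec$loading$mask)) {
    Cb <- stats::cov(Yb, use = "pairwise.complete.obs")
    Cb[!is.finite(Cb)] <- 0
    e <- eigen((Cb + t(Cb)) / 2, symmetric = TRUE)
    for (q in seq_len(spec$Q)) {
      free <- which(spec$loading$mask[, q])
      if (!length(free)) next
      v <- e$vectors[, min(q, ncol(e$vectors))] * sqrt(max(e$values[min(q, ncol(e$vectors))] / 2, 0.1))
      params$Lambda[free, q] <- v[free]
      a <- spec$loading$anchors[q]
      if (!is.na(a) && params$Lambda[a, q] < 0) params$Lambda[free, q] <- -params$Lambda[free, q]
      if (!is.na(a) && abs(params$Lambda[a, q]) < 1e-6) params$Lambda[a, q] <- 0.5
    }
  }
  params$Sigma_v <- lapply(params$Sigma_v, function(S) {
    if (length(S)) diag(0.1, nrow(S)) else S
  })
  treated <- d$arm == 1L
  pc_hat <- if (any(treated)) mean(d$receipt[treated]) else 0.5
  params$eta[] <- 0
  params$eta["(Intercept)"] <- qlogis(min(max(pc_hat, 0.02), 0.98))
  params
}

jitter_start <- function(theta0, lay, sd_var = 0.2, sd_other = 0.25) {
  var_idx <- c(block_range(lay, "xic"), block_range(lay, "xin"),
               block_range(lay, "t2c"), block_range(lay, "t2n"),
               block_range(lay, "sigv"))
  theta <- theta0
  theta[var_idx] <- theta[var_idx] + rnorm(length(var_idx), 0, sd_var)
  other <- setdiff(seq_along(theta), var_idx)
  theta[other] <- theta[other] + rnorm(length(other), 0, sd_other * abs(theta[other]) + 0.05)
  theta
}

#' Fit the latent-factor MCACE model by maximum likelihood
#'
#' @param data Long trial tibble (or `mcace_data`): columns `id`, `arm`,
#'   `receipt`, `visit`, optional `time`, and K outcome columns.
#' @param spec An [mcace_spec()].
#' @param covariates Optional per-subject baseline covariate table.
#' @param start Optional `mcace_params` starting values.
#' @param control A [fit_control()] list.
#' @param vcov `"original-fd"` (finite-difference observed information in the
#'   original parameterization, the default), `"transformed-delta"`
#'   (transformed-scale information with delta-method back-transform), or
#'   `"none"`.
#' @return An object of class `mcace_fit` with the MLE (`params`), maximized
#'   `loglik`, covariance of the free parameters (`vcov`), information
#'   criteria and convergence diagnostics. Use [tidy()], [glance()],
#'   [cace()], [pce()] on it.
#' @export
mcace_fit <- function(data, spec, covariates = NULL, start = NULL,
                      control = fit_control(),
                      vcov = c("original-fd", "transformed-delta", "none")) {
  vcov_method <- match.arg(vcov)
  findings <- validate_spec(spec, data = NULL)
  stop_on_findings(findings)
  d <- as_mcace_data(data, covariates, spec = spec)
  ctx <- make_context(d, spec)
  lay <- ctx$layout
  start <- start %||% initial_values(d, spec)
  theta0 <- par_pack(start, spec, "transformed")

  negll <- function(th) -cpp_mcace_loglik(th, ctx, TRUE)
  neggr <- function(th) -cpp_mcace_grad(th, ctx, TRUE)

  set.seed(control$seed)
  best <- NULL
  trace <- numeric(0)
  for (s in seq_len(control$n_restarts)) {
    th_s <- if (s == 1L) theta0 else jitter_start(theta0, lay)
    opt <- tryCatch(
      optim(th_s, negll, neggr, method = "BFGS",
            control = list(maxit = control$max_iter, reltol = control$rel_tol)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    trace <- c(trace, -opt$value)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("optimization failed in every restart")

  theta_hat <- best$par
  grad_norm <- max(abs(cpp_mcace_grad(theta_hat, ctx, TRUE)))
  params_hat <- par_unpack(theta_hat, spec, "transformed")
  params_hat <- canonicalize_signs(params_hat, spec)
  theta_hat <- par_pack(params_hat, spec, "transformed")
  theta_orig <- par_pack(params_hat, spec, "original")
  loglik <- cpp_mcace_loglik(theta_hat, ctx, TRUE)

  var_idx <- c(block_range(lay, "xic"), block_range(lay, "xin"),
               block_range(lay, "t2c"), block_range(lay, "t2n"))
  boundary <- lay$names[var_idx][theta_orig[var_idx] < control$boundary_tol]
  converged <- best$convergence == 0 && grad_norm <= max(control$grad_tol * (1 + abs(loglik)), 0.05)

  V <- NULL; vcov_used <- "none"; psd_projected <- FALSE
  if (vcov_method != "none") {
    use_transformed <- vcov_method == "transformed-delta" || length(boundary) > 0
    hv <- observed_information(params_hat, d, spec, control,
                               scale = if (use_transformed) "transformed" else "original",
                               ctx = ctx)
    V <- hv$vcov; psd_projected <- hv$psd_projected
    vcov_used <- if (use_transformed) "transformed-delta" else "original-fd"
  }

  p <- lay$p
  structure(
    list(
      params = params_hat, theta = theta_orig, loglik = loglik,
      vcov = V, vcov_method = vcov_used, psd_projected = psd_projected,
      converged = converged, grad_norm = grad_norm, n_free = p,
      n_subjects = d$N, aic = -2 * loglik + 2 * p,
      bic = -2 * loglik + log(d$N) * p,
      restart_trace = trace, boundary = boundary,
      spec = spec, data = d, control = control
    ),
    class = "mcace_fit"
  )
}

#' Observed-information covariance of the estimates
#'
#' Negative Hessian of the log-likelihood at the MLE, finite-differenced from
#' the analytic gradient, inverted to a covariance matrix. `scale =
#' "original"` differences in the original parameterization (variances as
#' variances); `scale = "transformed"` differences on the unconstrained scale
#' and maps back by the delta method, which is the valid choice when a
#' variance estimate sits near zero.
#'
#' @param params MLE as `mcace_params`.
#' @param data,spec Trial data and model specification.
#' @param control A [fit_control()] list (supplies the step size).
#' @param scale `"original"` or `"transformed"`.
#' @param ctx Internal likelihood context (rebuilt if missing).
#' @return List with `vcov`, `hessian`, `psd_projected`.
#' @export
observed_information <- function(params, data, spec, control = fit_control(),
                                 scale = c("original", "transformed"), ctx = NULL) {
  scale <- match.arg(scale)
  ctx <- ctx %||% make_context(as_mcace_data(data, spec = spec), spec)
  lay <- ctx$layout
  if (scale == "original") {
    th <- par_pack(params, spec, "original")
    H <- cpp_mcace_hessian(th, ctx, FALSE, control$hessian_step)
  } else {
    th_t <- par_pack(params, spec, "transformed")
    Ht <- cpp_mcace_hessian(th_t, ctx, TRUE, control$hessian_step)
    # delta method: V_orig = J V_trans J', J = d(original)/d(transformed)
    J <- transform_jacobian(th_t, spec)
    info_t <- -Ht
    Vt <- solve_information(info_t, lay)
    V <- J %*% Vt$vcov %*% t(J)
    dimnames(V) <- list(lay$names, lay$names)
    return(list(vcov = V, hessian = Ht, psd_projected = Vt$psd_projected))
  }
  info <- -H
  out <- solve_information(info, lay)
  dimnames(out$vcov) <- list(lay$names, lay$names)
  out
}

solve_information <- function(info, lay) {
  psd_projected <- FALSE
  ev <- eigen((info + t(info)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(abs(ev))) {
    if (min(abs(ev)) < 1e-12 * max(abs(ev))) {
      e <- eigen((info + t(info)) / 2, symmetric = TRUE)
      null_idx <- which(abs(e$values) < 1e-10 * max(abs(e$values)))
      weak <- unique(unlist(lapply(null_idx, function(i) {
        lay$names[which(abs(e$vectors[, i]) > 0.3)]
      })))
      stop("observed information is singular; weakly identified parameters: ",
           paste(weak, collapse = ", "), call. = FALSE)
    }
    info <- nearest_psd(info, 1e-8)
    psd_projected <- TRUE
  }
  list(vcov = solve((info + t(info)) / 2), psd_projected = psd_projected)
}

# Jacobian of original-scale parameters with respect to transformed-scale
# ones: diagonal exp() factors for log variances, and small numerically
# differenced blocks for the log-Cholesky random-effect entries.
transform_jacobian <- function(theta_trans, spec, step = 1e-6) {
  lay <- par_layout(spec)
  to_orig <- function(th) par_pack(par_unpack(th, spec, "transformed"), spec, "original")
  base <- to_orig(theta_trans)
  J <- diag(length(base))
  var_idx <- c(block_range(lay, "xic"), block_range(lay, "xin"),
               block_range(lay, "t2c"), block_range(lay, "t2n"), block_range(lay, "sigv"))
  for (i in var_idx) {
    tp <- theta_trans; tp[i] <- tp[i] + step
    tm <- theta_trans; tm[i] <- tm[i] - step
    J[, i] <- (to_orig(tp) - to_orig(tm)) / (2 * step)
  }
  J
}

#' @export
print.mcace_fit <- function(x, ...) {
  cat("<mcace_fit> K =", x$spec$K, "Q =", x$spec$Q,
      "| N =", x$n_subjects, "subjects\n")
  cat(sprintf("  logLik %.3f  AIC %.2f  BIC %.2f  (%d free parameters)\n",
              x$loglik, x$aic, x$bic, x$n_free))
  cat("  converged:", x$converged,
      sprintf(" max|grad| %.2e  vcov: %s\n", x$grad_norm, x$vcov_method))
  if (length(x$boundary)) cat("  boundary variance estimates:", paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.mcace_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free, nobs = object$n_subjects,
            class = "logLik")
}

#' @export
coef.mcace_fit <- function(object, ...) object$theta

#' @export
vcov.mcace_fit <- function(object, ...) object$vcov

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy parameter table of an MCACE fit
#'
#' @param x An `mcace_fit`.
#' @param conf_level Confidence level for Wald intervals.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.mcace_fit <- function(x, conf_level = 0.95, ...) {
  est <- x$theta
  se <- if (!is.null(x$vcov)) sqrt(pmax(diag(x$vcov), 0)) else rep(NA_real_, length(est))
  z <- est / se
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(z), p.value = unname(2 * pnorm(-abs(z))),
    conf.low = unname(est - zq * se), conf.high = unname(est + zq * se)
  )
}

#' One-row fit summary
#' @param x An `mcace_fit`.
#' @param ... Unused.
#' @export
glance.mcace_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, AIC = x$aic, BIC = x$bic, n_free = x$n_free,
    nobs = x$n_subjects, converged = x$converged, max_grad = x$grad_norm
  )
}
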