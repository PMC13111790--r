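# Parameter container and pack/unpack transforms.
#
# The free parameters are: measurement intercepts lambda0 (K per stratum),
# free loadings, stratum-specific fixed effects beta, random-intercept
# variances xi and residual variances tau2 (K per stratum), the random-effect
# covariance Sigma_v (block-diagonal over factors, shared across strata), and
# the compliance coefficients eta. The level-2 disturbance variance is fixed
# (not free). Two flat layouts are used: the "original" scale (variances and
# covariance entries as such) for reporting and observed-information standard
# errors, and the "transformed" scale (log variances, log-Cholesky Sigma_v
# blocks) on which the optimizer runs unconstrained.

#' Parameter template for a model specification
#'
#' Returns an `mcace_params` list with all free parameters at neutral values
#' (zero coefficients, unit variances, identity-scaled random-effect blocks),
#' to be filled in by name.
#'
#' @param spec An [mcace_spec()].
#' @return An `mcace_params` list with elements `lambda0` (K x 2 matrix,
#'   columns `c`, `n`), `Lambda` (K x Q), `beta` (list `c`, `n` of named
#'   vectors in factor-major order), `xi`, `tau2` (K x 2), `Sigma_v` (list of
#'   per-factor matrices), `eta` (named vector).
#' @export
par_template <- function(spec) {
  K <- spec$K; Q <- spec$Q
  lambda0 <- matrix(0, K, 2, dimnames = list(spec$outcome_names, c("c", "n")))
  Lambda <- spec$loading$fixed
  Lambda[spec$loading$mask] <- 1
  beta <- list(
    c = setNames(numeric(Q * length(spec$terms_c)),
                 unlist(lapply(seq_len(Q), function(q) paste0("beta[c,", q, ",", spec$terms_c, "]")))),
    n = setNames(numeric(Q * length(spec$terms_n)),
                 unlist(lapply(seq_len(Q), function(q) paste0("beta[n,", q, ",", spec$terms_n, "]"))))
  )
  xi <- matrix(1, K, 2, dimnames = list(spec$outcome_names, c("c", "n")))
  tau2 <- matrix(1, K, 2, dimnames = list(spec$outcome_names, c("c", "n")))
  Sigma_v <- lapply(spec$random, function(r) {
    rq <- length(r)
    if (rq == 0L) matrix(0, 0, 0) else diag(0.5, rq)
  })
  eta <- setNames(numeric(length(spec$compliance_covariates)), spec$compliance_covariates)
  structure(
    list(lambda0 = lambda0, Lambda = Lambda, beta = beta, xi = xi, tau2 = tau2,
         Sigma_v = Sigma_v, eta = eta),
    class = "mcace_params"
  )
}

#' Set fixed-effect coefficients by name
#'
#' Convenience setter: `set_beta(params, "c", q = 1, "D:t", 1.5)`.
#' @param params An `mcace_params` list.
#' @param stratum `"c"` or `"n"`.
#' @param q Factor index.
#' @param term Term name.
#' @param value Coefficient value.
#' @export
set_beta <- function(params, stratum, q, term, value) {
  nm <- paste0("beta[", stratum, ",", q, ",", term, "]")
  if (!nm %in% names(params$beta[[stratum]])) stop("no such coefficient: ", nm)
  params$beta[[stratum]][nm] <- value
  params
}

par_layout <- function(spec) {
  K <- spec$K; Q <- spec$Q
  mask_idx <- which(spec$loading$mask, arr.ind = TRUE)
  mask_idx <- mask_idx[order(mask_idx[, 2], mask_idx[, 1]), , drop = FALSE]
  rq <- vapply(spec$random, length, 1L)
  nms <- c(
    paste0("lambda0[c,", seq_len(K), "]"),
    paste0("lambda0[n,", seq_len(K), "]"),
    if (nrow(mask_idx)) paste0("lambda[", mask_idx[, 1], ",", mask_idx[, 2], "]"),
    unlist(lapply(seq_len(Q), function(q) paste0("beta[c,", q, ",", spec$terms_c, "]"))),
    unlist(lapply(seq_len(Q), function(q) paste0("beta[n,", q, ",", spec$terms_n, "]"))),
    paste0("xi[c,", seq_len(K), "]"), paste0("xi[n,", seq_len(K), "]"),
    paste0("tau2[c,", seq_len(K), "]"), paste0("tau2[n,", seq_len(K), "]"),
    unlist(lapply(seq_len(Q), function(q) {
      if (rq[q] == 0L) return(character(0))
      idx <- which(lower.tri(diag(rq[q]), diag = TRUE), arr.ind = TRUE)
      paste0("sigma_v[", q, ";", idx[, 1], ",", idx[, 2], "]")
    })),
    paste0("eta[", spec$compliance_covariates, "]")
  )
  sizes <- c(
    l0c = K, l0n = K, load = nrow(mask_idx),
    betac = Q * length(spec$terms_c), betan = Q * length(spec$terms_n),
    xic = K, xin = K, t2c = K, t2n = K,
    sigv = sum(rq * (rq + 1) / 2), eta = length(spec$compliance_covariates)
  )
  offsets <- setNames(c(0, cumsum(sizes))[seq_along(sizes)], names(sizes))
  list(names = nms, sizes = sizes, offsets = offsets,
       mask_idx = mask_idx, rq = rq, p = sum(sizes))
}

#' Number of free parameters
#' @param spec An [mcace_spec()].
#' @export
n_free_params <- function(spec) par_layout(spec)$p

block_range <- function(layout, block) {
  off <- layout$offsets[[block]]
  n <- layout$sizes[[block]]
  if (n == 0L) integer(0) else (off + 1L):(off + n)
}

#' Pack parameters into a flat vector
#'
#' @param params An `mcace_params` list.
#' @param spec The matching [mcace_spec()].
#' @param scale `"original"` (variances and `Sigma_v` entries as such) or
#'   `"transformed"` (log variances, log-Cholesky `Sigma_v` blocks) — the
#'   unconstrained scale the optimizer uses.
#' @return Named numeric vector.
#' @export
par_pack <- function(params, spec, scale = c("original", "transformed")) {
  scale <- match.arg(scale)
  lay <- par_layout(spec)
  mi <- lay$mask_idx
  loads <- if (nrow(mi)) params$Lambda[mi] else numeric(0)
  xi <- params$xi; tau2 <- params$tau2
  sigv <- unlist(lapply(seq_len(spec$Q), function(q) {
    S <- params$Sigma_v[[q]]
    if (length(S) == 0L) return(numeric(0))
    if (scale == "original") {
      S[lower.tri(S, diag = TRUE)]
    } else {
      L <- t(chol_safe(S + diag(1e-12, nrow(S))))
      diag(L) <- log(diag(L))
      L[lower.tri(L, diag = TRUE)]
    }
  }))
  vpart <- function(v) if (scale == "original") v else log(pmax(v, 1e-12))
  theta <- c(params$lambda0[, "c"], params$lambda0[, "n"], loads,
             params$beta$c, params$beta$n,
             vpart(xi[, "c"]), vpart(xi[, "n"]),
             vpart(tau2[, "c"]), vpart(tau2[, "n"]),
             sigv, params$eta)
  setNames(as.numeric(theta), lay$names)
}

#' Unpack a flat parameter vector
#'
#' Inverse of [par_pack()]; `par_unpack(par_pack(p, spec, s), spec, s)` is the
#' identity for valid parameter values.
#'
#' @param theta Flat numeric vector in the layout of [par_pack()].
#' @inheritParams par_pack
#' @return An `mcace_params` list.
#' @export
par_unpack <- function(theta, spec, scale = c("original", "transformed")) {
  scale <- match.arg(scale)
  lay <- par_layout(spec)
  stopifnot(length(theta) == lay$p)
  params <- par_template(spec)
  take <- function(block) unname(theta[block_range(lay, block)])
  params$lambda0[, "c"] <- take("l0c")
  params$lambda0[, "n"] <- take("l0n")
  if (nrow(lay$mask_idx)) params$Lambda[lay$mask_idx] <- take("load")
  params$beta$c[] <- take("betac")
  params$beta$n[] <- take("betan")
  vback <- function(v) if (scale == "original") v else exp(v)
  params$xi[, "c"] <- vback(take("xic"))
  params$xi[, "n"] <- vback(take("xin"))
  params$tau2[, "c"] <- vback(take("t2c"))
  params$tau2[, "n"] <- vback(take("t2n"))
  sv <- take("sigv")
  pos <- 0L
  for (q in seq_len(spec$Q)) {
    rq <- lay$rq[q]
    if (rq == 0L) next
    ntri <- rq * (rq + 1L) / 2L
    vals <- sv[(pos + 1L):(pos + ntri)]
    pos <- pos + ntri
    M <- matrix(0, rq, rq)
    M[lower.tri(M, diag = TRUE)] <- vals
    if (scale == "original") {
      M[upper.tri(M)] <- t(M)[upper.tri(M)]
      params$Sigma_v[[q]] <- M
    } else {
      diag(M) <- exp(diag(M))
      params$Sigma_v[[q]] <- M %*% t(M)
    }
  }
  params$eta[] <- take("eta")
  params
}

# Full (block-diagonal) random-effect covariance.
sigma_v_full <- function(params) block_diag(params$Sigma_v)

# Resolve the sign indeterminacy left by the zero restrictions: flipping the
# sign of factor q's loadings together with its fixed effects leaves the
# likelihood unchanged, so report the representative with a positive anchor.
canonicalize_signs <- function(params, spec) {
  for (q in seq_len(spec$Q)) {
    a <- spec$loading$anchors[q]
    if (is.na(a)) next
    if (params$Lambda[a, q] < 0) {
      params$Lambda[spec$loading$mask[, q], q] <- -params$Lambda[spec$loading$mask[, q], q]
      for (m in c("c", "n")) {
        terms <- stratum_terms(spec, m)
        if (length(terms)) {
          idx <- paste0("beta[", m, ",", q, ",", terms, "]")
          params$beta[[m]][idx] <- -params$beta[[m]][idx]
        }
      }
    }
  }
  params
}

#' @export
print.mcace_params <- function(x, ...) {
  cat("<mcace_params>\n")
  cat("Lambda:\n"); print(round(x$Lambda, 4))
  cat("beta (compliers):\n"); print(round(x$beta$c, 4))
  cat("beta (never-takers):\n"); print(round(x$beta$n, 4))
  cat("eta:\n"); print(round(x$eta, 4))
  invisible(x)
}
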