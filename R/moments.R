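# Closed-form marginal moments of the stacked outcome vector.
#
# Integrating the latent factors and all random effects out of the two-level
# model leaves, within a (stratum, arm), a multivariate normal with
#   mu    = lambda_m0 (x) 1_{J+1} + (Lambda (x) I_{J+1}) X_a beta_m
#   Sigma = (Lambda (x) I) Z Sigma_v Z' (Lambda (x) I)'        (random effects)
#         + eps_var (Lambda (x) I)(Lambda (x) I)'              (factor noise)
#         + diag(xi_m) (x) 1 1'                                (random intercepts)
#         + diag(tau2_m) (x) I                                 (measurement noise)
# in the outcome-major stacking convention ((x) = Kronecker product).

#' Marginal mean of the stacked outcomes
#'
#' @param params An `mcace_params` list.
#' @param spec An [mcace_spec()].
#' @param stratum `"c"` or `"n"`.
#' @param arm Assignment 0/1 (determines treatment receipt within stratum).
#' @param X Optional stacked fixed-effect design (defaults to
#'   [build_designs()] at the spec's visit schedule).
#' @return Numeric vector of length `K * (J+1)`.
#' @export
marginal_mu <- function(params, spec, stratum = c("c", "n"), arm = 1, X = NULL) {
  stratum <- match.arg(stratum)
  if (is.null(X)) {
    receipt <- if (stratum == "c" && arm == 1) 1 else 0
    X <- build_designs(spec, arm = arm, receipt = receipt, stratum = stratum)$X
  }
  beta <- params$beta[[stratum]]
  if (ncol(X) != length(beta)) stop("design/coefficient dimension mismatch")
  G <- kronecker(params$Lambda, diag(spec$J1))
  rep(unname(params$lambda0[, stratum]), each = spec$J1) +
    as.numeric(G %*% (X %*% beta))
}

#' Marginal covariance of the stacked outcomes
#'
#' @inheritParams marginal_mu
#' @param Z Optional stacked random-effect design.
#' @return Symmetric `K(J+1) x K(J+1)` matrix.
#' @export
marginal_sigma <- function(params, spec, stratum = c("c", "n"), Z = NULL) {
  stratum <- match.arg(stratum)
  if (is.null(Z)) Z <- build_designs(spec, arm = 0, receipt = 0, stratum = stratum)$Z
  Sv <- sigma_v_full(params)
  if (ncol(Z) != nrow(Sv)) stop("random-effect design/covariance dimension mismatch")
  ev <- eigen(Sv, symmetric = TRUE, only.values = TRUE)$values
  if (length(ev) && min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("Sigma_v is not positive semi-definite")
  }
  J1 <- spec$J1
  G <- kronecker(params$Lambda, diag(J1))
  GZ <- G %*% Z
  ones <- matrix(1, J1, J1)
  S <- GZ %*% Sv %*% t(GZ) +
    spec$eps_var * tcrossprod(G) +
    kronecker(diag(params$xi[, stratum], spec$K), ones) +
    kronecker(diag(params$tau2[, stratum], spec$K), diag(J1))
  (S + t(S)) / 2
}

#' Marginal moments for a (stratum, arm)
#'
#' @inheritParams marginal_mu
#' @return List with `mu`, `sigma`, `stratum`, `arm`.
#' @export
marginal_moments <- function(params, spec, stratum = c("c", "n"), arm = 1) {
  stratum <- match.arg(stratum)
  list(mu = marginal_mu(params, spec, stratum, arm),
       sigma = marginal_sigma(params, spec, stratum),
       stratum = stratum, arm = arm)
}
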