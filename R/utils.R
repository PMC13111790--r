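# Internal helpers shared across modules.

#' @importFrom stats setNames rnorm plogis qlogis pnorm qnorm pchisq qchisq
#'   optim dnorm var cov sd rbinom runif na.omit logLik AIC BIC coef vcov
#' @importFrom utils head modifyList
NULL

log_sum_exp <- function(a, b) {
  m <- pmax(a, b)
  # both -Inf: return -Inf without NaN
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

block_diag <- function(blocks) {
  blocks <- Filter(Negate(is.null), blocks)
  if (length(blocks) == 0L) return(matrix(0, 0, 0))
  blocks <- lapply(blocks, as.matrix)
  nr <- vapply(blocks, nrow, 1L)
  nc <- vapply(blocks, ncol, 1L)
  out <- matrix(0, sum(nr), sum(nc))
  r0 <- c(0L, cumsum(nr))
  c0 <- c(0L, cumsum(nc))
  for (i in seq_along(blocks)) {
    if (nr[i] > 0L && nc[i] > 0L) {
      out[r0[i] + seq_len(nr[i]), c0[i] + seq_len(nc[i])] <- blocks[[i]]
    }
  }
  out
}

# Central finite-difference Hessian of a scalar function; step is relative.
fd_hessian <- function(fn, x, step = 1e-4) {
  p <- length(x)
  h <- step * pmax(abs(x), 1)
  H <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (fn(xp) - 2 * fn(x) + fn(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
        H[i, j] <- H[j, i] <-
          (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

# Project a symmetric matrix to the nearest positive semi-definite matrix by
# eigenvalue clipping.
nearest_psd <- function(M, eps = 1e-10) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, eps * max(abs(e$values)))
  M2 <- e$vectors %*% (vals * t(e$vectors))
  (M2 + t(M2)) / 2
}

chol_safe <- function(S, jitter = 1e-10) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    S2 <- S + diag(jitter * mean(diag(S)), nrow(S))
    R <- tryCatch(chol(S2), error = function(e) NULL)
    if (is.null(R)) stop("covariance matrix is not positive definite (after jitter)")
  }
  R
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == round(x)
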