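# Model specification: loading structure, level-2 terms, design matrices.
#
# The two-level model ties K observed endpoints at visits j = 0..J to Q latent
# factors. Level 1 (measurement): y_ijk = lambda_m0k + sum_q lambda_kq U_qmij +
# b_mik + e_mijk within compliance stratum m. Level 2 (structural): U_qmij =
# x_qij(a)' beta_qm + z_qij' v_qmi + eps_qmij with Var(eps) fixed (default 1)
# for scale identification. Neither x nor z may contain an intercept; the
# location of the factors is absorbed by lambda_m0 and the random intercepts b.

TERM_VOCAB <- c("t", "t2", "D", "D:t", "D:t2")

term_involves_D <- function(term) term == "D" | startsWith(term, "D:")

# Evaluate one level-2 term at time t with treatment receipt D; covariate
# terms take the subject's baseline value (constant over visits, D-free).
eval_term <- function(term, t, D, covariates = NULL) {
  switch(term,
    "t"    = t,
    "t2"   = t^2,
    "D"    = rep(D, length(t)),
    "D:t"  = D * t,
    "D:t2" = D * t^2,
    {
      if (!is.null(covariates) && term %in% names(covariates)) {
        rep(as.numeric(covariates[[term]]), length(t))
      } else {
        stop("unknown level-2 term: '", term, "'", call. = FALSE)
      }
    }
  )
}

#' Loading structure for a confirmatory factor model
#'
#' Each outcome loads on exactly the factors named by `groups`: element `q` of
#' `groups` gives the indices of the outcomes with a free loading on factor
#' `q`. All other loadings are fixed (by default at 0). One anchor loading per
#' factor (by default the first free one) is constrained positive to resolve
#' the sign indeterminacy that the zero restrictions alone leave open.
#'
#' @param groups List of integer vectors, one per factor.
#' @param K Number of outcomes.
#' @param fixed_value Value of the non-free loadings (default 0).
#' @param anchors Optional integer vector, one outcome index per factor, naming
#'   the loading constrained positive.
#' @return A `loading_spec` object.
#' @export
#' @examples
#' loading_confirmatory(list(c(1, 2, 3, 5), c(4, 6)), K = 6)
loading_confirmatory <- function(groups, K, fixed_value = 0, anchors = NULL) {
  Q <- length(groups)
  mask <- matrix(FALSE, K, Q)
  for (q in seq_len(Q)) mask[groups[[q]], q] <- TRUE
  new_loading_spec(mask, fixed_value, mode = "confirmatory", anchors = anchors)
}

#' Loading structure for an exploratory factor model
#'
#' The generic identification constraint fixes \eqn{\lambda_{kq} = 0} for
#' \eqn{q > k}; all remaining loadings are free.
#'
#' @inheritParams loading_confirmatory
#' @param Q Number of factors.
#' @return A `loading_spec` object.
#' @export
loading_exploratory <- function(K, Q, anchors = NULL) {
  mask <- matrix(TRUE, K, Q)
  for (k in seq_len(K)) for (q in seq_len(Q)) if (q > k) mask[k, q] <- FALSE
  new_loading_spec(mask, 0, mode = "exploratory", anchors = anchors)
}

#' General loading mask
#'
#' @param mask K x Q logical matrix; `TRUE` entries are free loadings.
#' @param fixed_value Value (scalar or K x Q matrix) of the non-free entries.
#' @param mode `"confirmatory"` or `"exploratory"`.
#' @param anchors Optional per-factor outcome index of the positive anchor.
#' @return A `loading_spec` object.
#' @export
loading_mask <- function(mask, fixed_value = 0, mode = "confirmatory", anchors = NULL) {
  new_loading_spec(mask, fixed_value, mode, anchors)
}

new_loading_spec <- function(mask, fixed_value, mode, anchors) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  K <- nrow(mask); Q <- ncol(mask)
  fixed <- if (length(fixed_value) == 1L) matrix(fixed_value, K, Q) else as.matrix(fixed_value)
  if (is.null(anchors)) {
    anchors <- vapply(seq_len(Q), function(q) {
      free <- which(mask[, q])
      if (length(free)) free[1L] else NA_integer_
    }, 1L)
  }
  structure(
    list(mask = mask, fixed = fixed, mode = match.arg(mode, c("confirmatory", "exploratory")),
         anchors = as.integer(anchors)),
    class = "loading_spec"
  )
}

#' Level-2 (structural) model terms
#'
#' Names the fixed- and random-effect covariates of the latent-factor mixed
#' model, drawn from the vocabulary `t`, `t2`, `D`, `D:t`, `D:t2` plus named
#' baseline covariates. Intercepts are disallowed: factor location is
#' identified through the measurement intercepts and random intercepts.
#' Random-effect terms must be a subset of the fixed terms and may not involve
#' treatment receipt `D` (the random-effect design is shared across arms).
#'
#' Terms involving `D` are automatically absent from the never-taker
#' coefficient vector (never-takers have `D = 0` under both assignments, so
#' those coefficients would be unidentified). `baseline_balance = TRUE` also
#' drops the `D` main effect for compliers, encoding zero baseline difference
#' between randomized arms within the complier stratum.
#'
#' @param fixed Character vector of fixed-effect terms (shared across factors).
#' @param random Character vector of random-effect terms, or a list with one
#'   character vector per factor (a factor may have none).
#' @param baseline_balance Constrain the complier `D` main effect to zero.
#' @return A `level2_spec` object.
#' @export
#' @examples
#' level2_terms(fixed = c("t", "t2", "D", "D:t", "D:t2"),
#'              random = c("t", "t2"), baseline_balance = TRUE)
level2_terms <- function(fixed = c("t", "t2", "D", "D:t", "D:t2"),
                         random = "t",
                         baseline_balance = TRUE) {
  structure(
    list(fixed = fixed, random = random, baseline_balance = baseline_balance),
    class = "level2_spec"
  )
}

#' Specify a latent-factor MCACE model
#'
#' Collects the measurement structure (loading mask), the structural model for
#' the latent factors, the visit schedule, and the compliance-model covariates
#' into a validated model specification.
#'
#' @param K Number of outcomes.
#' @param Q Number of latent factors.
#' @param times Numeric visit times shared by all subjects (first entry is
#'   baseline). Default codes visits 0, 1, 2 in 3-month units.
#' @param loading A `loading_spec` (see [loading_confirmatory()]).
#' @param level2 A `level2_spec` (see [level2_terms()]).
#' @param compliance_covariates Names of baseline covariate columns entering
#'   the logistic compliance model; `"(Intercept)"` is always included first.
#' @param eps_var Variance of the level-2 disturbance, fixed for scale
#'   identification (default 1; the single-outcome comparator sets it to 0 and
#'   frees the residual variance instead).
#' @param outcome_names Optional outcome column names (default `y1..yK`).
#' @return An object of class `mcace_spec`.
#' @export
#' @examples
#' spec <- mcace_spec(
#'   K = 6, Q = 2,
#'   loading = loading_confirmatory(list(c(1, 2, 3, 5), c(4, 6)), K = 6),
#'   level2 = level2_terms(fixed = c("t", "t2", "D", "D:t", "D:t2"),
#'                         random = list(c("t", "t2"), character(0)))
#' )
mcace_spec <- function(K, Q,
                       times = c(0, 1, 2),
                       loading = loading_exploratory(K, Q),
                       level2 = level2_terms(),
                       compliance_covariates = character(0),
                       eps_var = 1,
                       outcome_names = paste0("y", seq_len(K))) {
  stopifnot(is_count(K), is_count(Q), length(times) >= 2L)
  random <- level2$random
  if (!is.list(random)) random <- rep(list(random), Q)
  if (length(random) != Q) stop("`random` must have one term set per factor")
  terms_c <- level2$fixed
  if (isTRUE(level2$baseline_balance)) terms_c <- setdiff(terms_c, "D")
  terms_n <- terms_c[!term_involves_D(terms_c)]
  cc <- setdiff(compliance_covariates, "(Intercept)")
  structure(
    list(
      K = K, Q = Q, times = as.numeric(times), J1 = length(times),
      loading = loading, level2 = level2,
      terms_c = terms_c, terms_n = terms_n, random = random,
      compliance_covariates = c("(Intercept)", cc),
      eps_var = eps_var, outcome_names = outcome_names
    ),
    class = "mcace_spec"
  )
}

#' @export
print.mcace_spec <- function(x, ...) {
  cat("<mcace_spec> K =", x$K, "outcomes, Q =", x$Q, "factors,",
      x$J1, "visits at t =", paste(x$times, collapse = ", "), "\n")
  cat("  loading:", x$loading$mode, "with", sum(x$loading$mask), "free entries\n")
  cat("  fixed terms (compliers):", paste(x$terms_c, collapse = ", "), "\n")
  cat("  fixed terms (never-takers):", paste(x$terms_n, collapse = ", "), "\n")
  rnd <- vapply(x$random, function(r) if (length(r)) paste(r, collapse = ", ") else "none", "")
  cat("  random terms by factor:", paste(rnd, collapse = " | "), "\n")
  cat("  compliance covariates:", paste(x$compliance_covariates, collapse = ", "), "\n")
  invisible(x)
}

stratum_terms <- function(spec, stratum) {
  if (stratum == "c") spec$terms_c else spec$terms_n
}

# (J+1) x n_terms per-factor design block at the given receipt value.
design_block <- function(terms, times, D, covariates = NULL) {
  if (length(terms) == 0L) return(matrix(0, length(times), 0L))
  out <- vapply(terms, function(tm) eval_term(tm, times, D, covariates), numeric(length(times)))
  out <- matrix(out, nrow = length(times), dimnames = list(NULL, terms))
  out
}

#' Stacked fixed- and random-effect design matrices
#'
#' Builds the stacked level-2 designs for one subject: `X` has `Q * (J+1)`
#' rows in factor-major, time-minor order (matching the stacking of the latent
#' factor vector) and one column per free coefficient of the requested
#' stratum; `Z` is the analogous random-effect design. Within a stratum the
#' design depends on the assignment only through the treatment receipt, so
#' control-arm rows have all treatment columns equal to zero.
#'
#' @param spec An [mcace_spec()].
#' @param times Visit times (defaults to the schedule in `spec`).
#' @param arm Assignment (0/1).
#' @param receipt Treatment receipt `D_i(arm)`; under no control-arm access
#'   this is 0 whenever `arm = 0` and always 0 for never-takers.
#' @param stratum `"c"` (complier) or `"n"` (never-taker); determines which
#'   coefficients are free (treatment terms are dropped for never-takers).
#' @param covariates Optional named list/row of baseline covariate values for
#'   covariate terms.
#' @return List with elements `X` and `Z`.
#' @export
build_designs <- function(spec, times = spec$times, arm = 1, receipt = arm,
                          stratum = c("c", "n"), covariates = NULL) {
  stratum <- match.arg(stratum)
  stopifnot(arm %in% c(0, 1))
  if (arm == 0 && receipt != 0) stop("receipt must be 0 in the control arm (no access to treatment)")
  if (stratum == "n" && receipt != 0) stop("never-takers have receipt 0 under both assignments")
  terms <- stratum_terms(spec, stratum)
  if (any(terms %in% c("1", "(Intercept)")) ||
      any(unlist(spec$random) %in% c("1", "(Intercept)"))) {
    stop("level-2 terms must not include an intercept (location normalization)")
  }
  X0 <- design_block(terms, times, D = receipt, covariates = covariates)
  Xb <- replicate(spec$Q, X0, simplify = FALSE)
  X <- block_diag(Xb)
  if (ncol(X) > 0) {
    colnames(X) <- unlist(lapply(seq_len(spec$Q), function(q) paste0("beta[", stratum, ",", q, ",", terms, "]")))
  }
  Zb <- lapply(spec$random, function(r) design_block(r, times, D = 0, covariates = covariates))
  Z <- block_diag(Zb)
  if (ncol(Z) > 0) {
    cn <- unlist(lapply(seq_len(spec$Q), function(q) {
      r <- spec$random[[q]]
      if (length(r)) paste0("v[", q, ",", r, "]") else character(0)
    }))
    colnames(Z) <- cn
  }
  if (nrow(Z) == 0L) Z <- matrix(0, spec$Q * length(times), 0L)
  list(X = X, Z = Z)
}

#' Validate a model specification (optionally against data)
#'
#' Structural checks of the identification constraints: no intercepts among
#' level-2 terms, exploratory upper-triangular zero restrictions, sign anchors
#' present, random terms nested in fixed terms and free of `D`, and (with
#' data) existence of referenced columns. Findings are returned, not thrown,
#' so callers decide how to react; an empty result means the specification is
#' accepted.
#'
#' @param spec An [mcace_spec()].
#' @param data Optional trial data (long tibble or `mcace_data`).
#' @return A tibble with columns `severity` (`"error"`/`"warning"`) and
#'   `message`; zero rows when no findings.
#' @export
validate_spec <- function(spec, data = NULL) {
  findings <- list()
  add <- function(severity, message) {
    findings[[length(findings) + 1L]] <<- tibble::tibble(severity = severity, message = message)
  }
  all_terms <- unique(c(spec$level2$fixed, unlist(spec$random)))
  if (any(all_terms %in% c("1", "(Intercept)"))) {
    add("error", "level-2 terms include an intercept; intercepts are excluded by the location normalization (factor means are absorbed by the measurement intercepts)")
  }
  if (spec$loading$mode == "exploratory") {
    bad <- which(spec$loading$mask & upper.tri(spec$loading$mask), arr.ind = TRUE)
    if (nrow(bad)) {
      add("error", paste0("exploratory loading structure must fix lambda[k,q] = 0 for q > k; free entries found at ",
                          paste(sprintf("(%d,%d)", bad[, 1], bad[, 2]), collapse = ", ")))
    }
  }
  for (q in seq_len(spec$Q)) {
    free <- which(spec$loading$mask[, q])
    fixed_vals <- spec$loading$fixed[!spec$loading$mask[, q], q]
    if (length(free) == 0L && all(fixed_vals == 0)) {
      add("warning", paste0("factor ", q, " has no free loadings and all fixed loadings are zero; it is unidentified"))
    }
    if (length(free) > 0L && (is.na(spec$loading$anchors[q]) || !spec$loading$mask[spec$loading$anchors[q], q])) {
      add("error", paste0("factor ", q, " has no positive sign anchor among its free loadings"))
    }
  }
  if (spec$Q >= spec$K && spec$K > 1L) {
    add("warning", paste0("Q = ", spec$Q, " factors with only K = ", spec$K,
                          " outcomes; a parsimonious model needs Q well below K"))
  }
  for (q in seq_len(spec$Q)) {
    r <- spec$random[[q]]
    if (!all(r %in% spec$level2$fixed)) {
      add("error", paste0("random terms for factor ", q, " are not a subset of the fixed terms"))
    }
    if (any(term_involves_D(r))) {
      add("error", paste0("random terms for factor ", q, " involve treatment receipt; the random-effect design is shared across arms"))
    }
  }
  known <- c(TERM_VOCAB, spec$compliance_covariates)
  unknown <- setdiff(spec$level2$fixed, known)
  if (!is.null(data)) {
    d <- as_mcace_data(data, spec = NULL)
    unknown <- setdiff(unknown, colnames(d$W))
    miss_cc <- setdiff(setdiff(spec$compliance_covariates, "(Intercept)"), colnames(d$W))
    if (length(miss_cc)) {
      add("error", paste0("compliance covariates not present in data: ", paste(miss_cc, collapse = ", ")))
    }
    if (ncol(d$Y) != spec$K * spec$J1) {
      add("error", paste0("data have ", ncol(d$Y) / d$J1, " outcomes x ", d$J1,
                          " visits; spec expects K = ", spec$K, ", visits = ", spec$J1))
    }
  } else {
    unknown <- setdiff(unknown, TERM_VOCAB)
    unknown <- setdiff(unknown, setdiff(spec$compliance_covariates, "(Intercept)"))
    # without data, any non-vocabulary name is assumed to be a baseline covariate
    unknown <- character(0)
  }
  if (length(unknown)) {
    add("error", paste0("unknown level-2 terms: ", paste(unknown, collapse = ", ")))
  }
  if (length(findings) == 0L) {
    return(tibble::tibble(severity = character(0), message = character(0)))
  }
  dplyr::bind_rows(findings)
}

stop_on_findings <- function(findings) {
  errs <- findings$message[findings$severity == "error"]
  if (length(errs)) stop("invalid model specification:\n  - ", paste(errs, collapse = "\n  - "), call. = FALSE)
  for (w in findings$message[findings$severity == "warning"]) warning(w, call. = FALSE)
  invisible(NULL)
}
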