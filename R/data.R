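# Trial data container.
#
# User-facing data are tidy: one row per subject-visit with columns
# id, arm, receipt, visit, time, y1..yK, plus a one-row-per-subject baseline
# covariate table. Internally the stacked outcome vector per subject follows
# the Kronecker convention of the marginal moments: outcome-major blocks of
# length J+1, i.e. entry (k-1)*(J+1) + j + 1 holds outcome k at visit j.

#' Assemble trial data for MCACE fitting
#'
#' @param outcomes Long tibble/data frame with columns `id`, `arm` (0/1),
#'   `receipt` (0/1; used in the treated arm only), `visit` (0-based index),
#'   optional `time`, and outcome columns (any columns not otherwise named).
#' @param covariates Optional one-row-per-subject data frame with `id` and
#'   baseline covariate columns for the compliance model.
#' @param outcome_cols Optional character vector naming the outcome columns;
#'   by default every column other than the reserved ones.
#' @return An object of class `mcace_data` with the stacked outcome matrix
#'   `Y` (subjects x K(J+1), `NA` for missing cells), `arm`, `receipt`,
#'   `times`, covariate matrix `W` (with intercept column), and `id`.
#' @export
mcace_data <- function(outcomes, covariates = NULL, outcome_cols = NULL) {
  outcomes <- as.data.frame(outcomes)
  reserved <- c("id", "arm", "receipt", "visit", "time")
  if (!all(c("id", "arm", "visit") %in% names(outcomes))) {
    stop("`outcomes` needs columns id, arm, visit")
  }
  if (is.null(outcome_cols)) outcome_cols <- setdiff(names(outcomes), reserved)
  if (length(outcome_cols) == 0L) stop("no outcome columns found")
  if (!all(outcomes$arm %in% c(0, 1))) stop("arm must be 0/1")
  if (!"receipt" %in% names(outcomes)) outcomes$receipt <- 0
  outcomes$receipt[outcomes$arm == 0] <- 0  # undefined in the control arm
  if (!all(outcomes$receipt %in% c(0, 1))) stop("receipt must be 0/1")

  visits <- sort(unique(outcomes$visit))
  J1 <- length(visits)
  if ("time" %in% names(outcomes)) {
    tm <- unique(outcomes[, c("visit", "time")])
    tm <- tm[order(tm$visit), ]
    if (nrow(tm) != J1) stop("visit/time mapping is not one-to-one")
    times <- tm$time
  } else {
    times <- as.numeric(visits)
  }
  ids <- unique(outcomes$id)
  N <- length(ids)
  K <- length(outcome_cols)
  Y <- matrix(NA_real_, N, K * J1)
  colnames(Y) <- unlist(lapply(outcome_cols, function(k) paste0(k, "@v", visits)))
  arm <- receipt <- integer(N)
  row_i <- match(outcomes$id, ids)
  col_j <- match(outcomes$visit, visits)
  for (k in seq_len(K)) {
    Y[cbind(row_i, (k - 1L) * J1 + col_j)] <- outcomes[[outcome_cols[k]]]
  }
  agg <- outcomes[!duplicated(outcomes$id), c("id", "arm", "receipt")]
  agg <- agg[match(ids, agg$id), ]
  arm <- as.integer(agg$arm)
  receipt <- as.integer(agg$receipt)
  if (any(rowSums(!is.na(Y)) == 0L)) stop("subjects with all outcomes missing are not allowed")

  W <- matrix(1, N, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (!"id" %in% names(covariates)) stop("`covariates` needs an id column")
    cv <- covariates[match(ids, covariates$id), setdiff(names(covariates), "id"), drop = FALSE]
    if (anyNA(cv)) stop("baseline covariates must be fully observed")
    W <- cbind(W, as.matrix(cv))
  }
  structure(
    list(Y = Y, arm = arm, receipt = receipt, times = times, W = W,
         id = ids, K = K, J1 = J1, N = N, outcome_names = outcome_cols),
    class = "mcace_data"
  )
}

#' Coerce to `mcace_data`
#' @param x A long data frame or an `mcace_data` object.
#' @param covariates Optional covariate table (ignored if `x` already is
#'   `mcace_data`).
#' @param spec Optional spec used to check outcome count.
#' @export
as_mcace_data <- function(x, covariates = NULL, spec = NULL) {
  d <- if (inherits(x, "mcace_data")) x else mcace_data(x, covariates)
  if (!is.null(spec) && (d$K != spec$K || d$J1 != spec$J1)) {
    stop("data have K = ", d$K, ", visits = ", d$J1,
         " but spec expects K = ", spec$K, ", visits = ", spec$J1)
  }
  d
}

#' @export
print.mcace_data <- function(x, ...) {
  cat("<mcace_data>", x$N, "subjects,", x$K, "outcomes,", x$J1, "visits\n")
  cat("  treated:", sum(x$arm == 1), "(receipt:", sum(x$receipt == 1), ") control:", sum(x$arm == 0), "\n")
  cat("  missing outcome cells:", sum(is.na(x$Y)), "/", length(x$Y), "\n")
  invisible(x)
}

#' Convert `mcace_data` back to a long tibble
#' @param data An `mcace_data` object.
#' @return Long tibble with one row per subject-visit.
#' @export
as_long_tibble <- function(data) {
  d <- as_mcace_data(data)
  out <- tidyr::expand_grid(id = d$id, visit = seq_len(d$J1) - 1L)
  out$time <- d$times[out$visit + 1L]
  i <- match(out$id, d$id)
  out$arm <- d$arm[i]
  out$receipt <- d$receipt[i]
  for (k in seq_len(d$K)) {
    out[[d$outcome_names[k]]] <- d$Y[cbind(i, (k - 1L) * d$J1 + out$visit + 1L)]
  }
  dplyr::relocate(out, "id", "arm", "receipt", "visit", "time")
}

# Observed (arm, receipt) pattern per subject: S11 treated compliers,
# S10 treated never-takers, S00 all controls.
subject_group <- function(data) {
  ifelse(data$arm == 1L, ifelse(data$receipt == 1L, "S11", "S10"), "S00")
}
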