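# ggplot2 displays for result tables.

#' Plot power / type-I error curves
#'
#' Rejection proportion against the effect size, one line per method,
#' faceted by sample size and compliance rate, with binomial Monte-Carlo
#' error bars.
#'
#' @param object A [run_power_study()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mcace_power <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  ggplot2::ggplot(object, ggplot2::aes(x = .data$effect, y = .data$reject_rate,
                                       colour = .data$method)) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dotted", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$reject_rate - 2 * .data$mc_se, 0),
      ymax = pmin(.data$reject_rate + 2 * .data$mc_se, 1))) +
    ggplot2::facet_grid(.data$n_subjects ~ .data$p_compliance,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "complier treatment-by-time coefficient",
                  y = "rejection proportion", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot estimated factor effects over time
#'
#' CACE (or PCE) point estimates with 95% intervals per factor and visit.
#'
#' @param object A table from [cace()] or [pce()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mcace_estimands <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ factor, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time", y = "effect on latent factor") +
    ggplot2::theme_minimal()
}

#' Plot recovery-study calibration
#'
#' Per-parameter bias with Monte-Carlo intervals (left) and the ratio of the
#' mean model-based SE to the empirical SD (right).
#'
#' @param object A [run_recovery_study()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mcace_recovery <- function(object, ...) {
  df <- dplyr::mutate(object, term = factor(.data$term, levels = rev(.data$term)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bias, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted", colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$bias - 2 * .data$mc_se,
                                          xmax = .data$bias + 2 * .data$mc_se)) +
    ggplot2::labs(x = "bias (with 2 Monte-Carlo SEs)", y = NULL) +
    ggplot2::theme_minimal()
}
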