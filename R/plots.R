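# ggplot2 views of the result objects.

#' Forest-style plot of a fitted debt model
#'
#' Point estimates with 95% Wald intervals for each coefficient (the pooled
#' mean, or each moderator category).
#'
#' @param object A `"debt_fit"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot debt_fit
#' @export
autoplot.debt_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci.low,
                                          xmax = .data$ci.high)) +
    ggplot2::labs(x = "per-annum debt ratio (% of reference)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Category panels of a full analysis
#'
#' Per-category pooled debts with 95% intervals, faceted by metric and
#' moderator — the tabular analogue of a per-category forest figure.
#'
#' @param object A `"recovery_report"`.
#' @param ... Unused.
#' @return A ggplot, or `NULL` when the report holds no category estimates.
#' @method autoplot recovery_report
#' @export
autoplot.recovery_report <- function(object, ...) {
  if (is.null(object$categories)) return(NULL)
  ggplot2::ggplot(object$categories,
                  ggplot2::aes(x = .data$mean, y = .data$label)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::facet_grid(ggplot2::vars(.data$moderator),
                        ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "per-annum debt ratio (% of reference)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Strategy-selection view
#'
#' Mann-Whitney p-values of the nine zero-handling strategies against the
#' zero-free remainder of the database; the dashed line is the p = 0.05
#' acceptance threshold and the filled point the selected strategy.
#'
#' @param object A `"strategy_report"` from [select_zero_strategy()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot strategy_report
#' @export
autoplot.strategy_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$strategy), y = .data$p_value)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$selected), size = 3) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed") +
    ggplot2::labs(x = "zero-handling strategy", y = "Mann-Whitney p-value") +
    ggplot2::theme_minimal()
}
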