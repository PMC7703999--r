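# ggplot2 views of the result objects.

#' Plot a group comparison table
#'
#' Bars of -log10 p per feature, faceted by analysis family, with each
#' family's Bonferroni threshold as a dashed line; significant features
#' are filled.
#'
#' @param object A `dream_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dream_comparison <- function(object, ...) {
  df <- object$comparison
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$feature, -.data$p_value),
                                   y = -log10(.data$p_value),
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = -log10(.data$threshold)),
                        linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$family), scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey70"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  title = "Pandemic vs control dream features",
                  subtitle = "dashed line: family Bonferroni threshold") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot canonical coefficients
#'
#' Coefficient bars of the first canonical pair for both variable sets.
#'
#' @param object A `dream_cca` object.
#' @param pair Which canonical pair to show (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dream_cca <- function(object, pair = 1, ...) {
  df <- dplyr::filter(tidy(object), .data$pair == !!pair)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable, y = .data$coefficient,
                                   fill = .data$set)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$set), scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(x = "#2166ac", y = "#b2182b")) +
    ggplot2::labs(x = NULL, y = "canonical coefficient (standardized)",
                  title = sprintf("Canonical pair %d (r = %.3f, p = %.4f)",
                                  pair, object$correlations[pair], object$p_value)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot longitudinal feature drift
#'
#' Scatter of a feature against days since lockdown over pandemic reports,
#' with a linear trend.
#'
#' @param per_report Per-report feature tibble.
#' @param feature Feature column name.
#' @return A ggplot object.
#' @export
plot_longitudinal <- function(per_report, feature) {
  df <- dplyr::filter(per_report, .data$group == "pandemic",
                      !is.na(.data$days_since_lockdown), !is.na(.data[[feature]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$days_since_lockdown,
                                   y = .data[[feature]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         color = "#2166ac") +
    ggplot2::labs(x = "days since lockdown", y = feature) +
    ggplot2::theme_minimal()
}
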