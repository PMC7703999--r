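# broom-style tidy()/glance() methods for fitted objects.

#' @importFrom broom tidy glance
NULL

#' Tidy a canonical correlation fit
#'
#' One row per variable per canonical pair, with the standardized and
#' raw-scale coefficients.
#'
#' @param x A `dream_cca` object.
#' @param ... Unused.
#' @return A tibble: `pair`, `set` (`"x"` or `"y"`), `variable`,
#'   `coefficient`, `coefficient_raw`, `correlation`.
#' @export
tidy.dream_cca <- function(x, ...) {
  k <- length(x$correlations)
  one_set <- function(std, raw, set) {
    purrr::map_dfr(seq_len(k), function(j) {
      tibble::tibble(pair = j, set = set, variable = rownames(std),
                     coefficient = std[, j], coefficient_raw = raw[, j],
                     correlation = x$correlations[j])
    })
  }
  dplyr::bind_rows(
    one_set(x$x_coefficients, x$x_coefficients_raw, "x"),
    one_set(x$y_coefficients, x$y_coefficients_raw, "y")
  )
}

#' Glance at a canonical correlation fit
#'
#' @param x A `dream_cca` object.
#' @param ... Unused.
#' @return A one-row tibble: `first_correlation`, `statistic` (Bartlett
#'   chi-square), `df`, `p_value`, `n`.
#' @export
glance.dream_cca <- function(x, ...) {
  tibble::tibble(first_correlation = x$correlations[1],
                 statistic = x$statistic, df = x$df,
                 p_value = x$p_value, n = x$n)
}

#' Tidy a regression fit
#'
#' @param x A `dream_ols` object.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value` (per-term t tests, intercept included).
#' @export
tidy.dream_ols <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
                 statistic = sm[, 3], p_value = sm[, 4])
}

#' Glance at a regression fit
#'
#' @param x A `dream_ols` object.
#' @param ... Unused.
#' @return A one-row tibble: `r_squared`, `statistic` (overall F),
#'   `p_value`, `n`, `n_dropped`.
#' @export
glance.dream_ols <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, statistic = x$statistic,
                 p_value = x$p_value, n = x$n, n_dropped = x$n_dropped)
}
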