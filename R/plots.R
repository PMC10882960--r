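#' Plot the effect-factor regression
#'
#' Scatter of country-level PDF against ASF with bubble size proportional to
#' the regression weight (log10 area) and the fitted quantile line.
#'
#' @param object An `invacf_ef` from [weighted_quantile_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.invacf_ef <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$w),
                        alpha = 0.5, colour = "steelblue") +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, colour = "grey30") +
    ggplot2::scale_size_continuous(name = "weight (log10 area)") +
    ggplot2::labs(
      x = "Alien species fraction (ASF)",
      y = "Potentially disappeared fraction (PDF)",
      title = sprintf("Quantile regression at tau = %.2f: slope = %.3g",
                      object$tau, object$slope)
    ) +
    ggplot2::theme_minimal()
}

#' Plot residual diagnostics of the count model
#'
#' Pearson residuals against fitted means on a log1p axis, the standard check
#' for heteroscedasticity of the introduction-count fit.
#'
#' @param object An `invacf_glmm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.invacf_glmm <- function(object, ...) {
  d <- tibble::tibble(
    fitted = stats::fitted(object$model),
    residual = stats::residuals(object$model, type = "pearson")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = log1p(.data$fitted),
                                  y = .data$residual)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::labs(x = "log1p(fitted mean)", y = "Pearson residual") +
    ggplot2::theme_minimal()
}

#' Distribution of fate or characterization factors
#'
#' Histogram of the factor values on a log10 axis, facetted by kind
#' (marginal / average); factors typically span many orders of magnitude.
#'
#' @param factors Tibble with columns `kind` and either `value` (fate
#'   factors) or `regional_cf` / `global_cf` (characterization factors).
#' @param value Column to plot.
#' @return A ggplot object.
#' @export
plot_factor_distribution <- function(factors, value = "value") {
  assert_columns(factors, c("kind", value), "`factors`")
  d <- factors[is.finite(factors[[value]]) & factors[[value]] > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data[[value]]))) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~kind) +
    ggplot2::labs(x = sprintf("log10(%s)", value), y = "pairs") +
    ggplot2::theme_minimal()
}

#' Plot an impact comparison against the reference stressor
#'
#' Side-by-side bars of alien-species and reference impacts per route.
#'
#' @param comparison Tibble from [compare_with_reference()], optionally with a
#'   `route` column naming each row.
#' @return A ggplot object.
#' @export
plot_comparison <- function(comparison) {
  assert_columns(comparison, c("alien_impact", "reference_impact"),
                 "`comparison`")
  d <- comparison
  if (!"route" %in% names(d)) d$route <- paste("route", seq_len(nrow(d)))
  long <- tidyr::pivot_longer(
    d, c("alien_impact", "reference_impact"),
    names_to = "stressor", values_to = "impact"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$route, y = .data$impact,
                                     fill = .data$stressor)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "PDF x year") +
    ggplot2::theme_minimal()
}
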