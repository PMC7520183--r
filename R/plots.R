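#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of per-sample PSi values
#'
#' @param psi_tbl Per-sample tibble from [group_psi()].
#' @param transformed Plot logit-transformed values instead? Default `FALSE`.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_psi_distribution <- function(psi_tbl, transformed = FALSE, bins = 30) {
  col <- if (transformed) "logit_psi" else "psi"
  lab <- if (transformed) "logit(PSi)" else "PSi"
  ggplot2::ggplot(psi_tbl, ggplot2::aes(x = .data[[col]])) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::labs(x = lab, y = "Number of samples",
                  title = paste("Distribution of", lab)) +
    ggplot2::theme_minimal()
}

#' Seasonal mean PSi by sex
#'
#' Mean logit-transformed PSi with normal-approximation 95% CIs by season
#' and sex; lower values mean more specialization.
#'
#' @param psi_tbl Per-sample tibble from [group_psi()] (retained samples).
#' @return A ggplot object.
#' @export
plot_seasonal_psi <- function(psi_tbl) {
  d <- psi_tbl |>
    dplyr::filter(.data$season != "out-of-window") |>
    dplyr::group_by(.data$season, .data$sex) |>
    dplyr::summarise(
      m = mean(.data$logit_psi),
      se = stats::sd(.data$logit_psi) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(season = factor(.data$season, c("spring", "summer", "fall")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$season, y = .data$m,
                                  colour = .data$sex, group = .data$sex)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$m - 1.96 * .data$se,
                   ymax = .data$m + 1.96 * .data$se),
      width = 0.15, position = ggplot2::position_dodge(0.3)
    ) +
    ggplot2::labs(x = NULL, y = "Mean logit(PSi) ± 95% CI", colour = "Sex") +
    ggplot2::theme_minimal()
}

#' Model comparison plot
#'
#' Akaike weights of the model family, ordered by AIC.
#'
#' @param comparison Output of [compare_psi_models()].
#' @return A ggplot object.
#' @export
plot_model_comparison <- function(comparison) {
  d <- dplyr::mutate(comparison,
                     predictors = factor(.data$predictors,
                                         levels = rev(.data$predictors)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$wi, y = .data$predictors)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "Akaike weight", y = NULL) +
    ggplot2::theme_minimal()
}

#' Residual diagnostics for a fitted PSi mixed model
#'
#' @param object A `psi_lmm` object.
#' @param ... Unused.
#' @return A ggplot object (fitted values vs residuals).
#' @export
autoplot.psi_lmm <- function(object, ...) {
  d <- tibble::tibble(fitted = stats::fitted(object$fit),
                      residual = stats::residuals(object$fit))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fitted, y = .data$residual)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Fitted logit(PSi)", y = "Residual",
                  title = object$label) +
    ggplot2::theme_minimal()
}
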