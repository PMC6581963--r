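#' Plot fitted marker washout curves
#'
#' Observed log concentrations against hours post-dose, one panel per
#' animal, with the fitted per-diet curve (including the animal's random
#' intercept) overlaid.
#'
#' @param object A [fit_decay()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  dat <- object$data
  grid <- tidyr::expand_grid(
    object$coefficients,
    object$ranef,
    time_h = seq(min(dat$time_h), max(dat$time_h), length.out = 60)
  ) |>
    dplyr::semi_join(
      dplyr::distinct(dat, .data$cow_id, .data$diet),
      by = c("cow_id", "diet")
    ) |>
    dplyr::mutate(
      log_conc = .data$intercept + .data$a_cow + .data$slope * .data$time_h +
        .data$quad * .data$time_h^2
    )
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_h, .data$log_conc,
                                    colour = .data$diet)) +
    ggplot2::geom_point(size = 1.6, alpha = 0.8) +
    ggplot2::geom_line(data = grid) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cow_id)) +
    ggplot2::labs(
      x = "Hours post-dose",
      y = sprintf("log marker concentration (%s phase)", object$phase),
      colour = "Diet"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cow-adjusted regression
#'
#' Scatter of the raw observations coloured by cow with the fixed-effect
#' (population) regression line; the annotation reports the slope, its
#' standard error and the marginal R-squared.
#'
#' @param object A [cow_adjusted_regression()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cow_regression
#' @export
autoplot.cow_regression <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cow), size = 2) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope) +
    ggplot2::labs(
      x = object$x_name, y = object$y_name, colour = "Cow",
      subtitle = sprintf("slope %.3g ± %.3g, marginal R² %.2f",
                         object$slope, object$se, object$r2_marginal)
    ) +
    ggplot2::theme_minimal()
}
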