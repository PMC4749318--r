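# Report plots ------------------------------------------------------------
#
# Prediction surfaces mirror the standard presentation for these analyses:
# the demographic rate against the dry-season greenness deviation, one
# panel/line per wet-season deviation level, with delta-method ribbons.

dev_grid <- function(wet_levels) {
  tidyr::expand_grid(
    evi_d_dev = seq(-2, 2, by = 0.1),
    wet = wet_levels
  )
}

#' Plot predicted productivity against greenness deviations
#'
#' @param object A converged `vg_prod_fit`.
#' @param wet_levels Standardized lagged wet-season deviation levels to draw
#'   one curve each for.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vg_prod_fit
#' @export
autoplot.vg_prod_fit <- function(object, wet_levels = c(-1, 0, 1), ...) {
  grid <- dev_grid(wet_levels)
  pred <- predict_productivity(
    object, tibble(evi_d_dev = grid$evi_d_dev, evi_w_dev_prev = grid$wet)
  )
  pred$wet <- factor(grid$wet)
  ggplot2::ggplot(pred, ggplot2::aes(.data$evi_d_dev, .data$estimate,
                                     colour = .data$wet, fill = .data$wet)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Dry-season EVI deviation (SD)",
      y = "P(young | aged capture)",
      colour = "Wet-season EVI\ndeviation (prev., SD)",
      fill = "Wet-season EVI\ndeviation (prev., SD)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot predicted apparent survival against greenness deviations
#'
#' @param object A converged `vg_barker_fit`.
#' @inheritParams autoplot.vg_prod_fit
#' @return A ggplot object.
#' @method autoplot vg_barker_fit
#' @export
autoplot.vg_barker_fit <- function(object, wet_levels = c(-1, 0, 1), ...) {
  grid <- dev_grid(wet_levels)
  pred <- predict_survival(
    object, tibble(evi_d_dev = grid$evi_d_dev, evi_w_dev = grid$wet)
  )
  pred$wet <- factor(grid$wet)
  ggplot2::ggplot(pred, ggplot2::aes(.data$evi_d_dev, .data$estimate,
                                     colour = .data$wet, fill = .data$wet)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Dry-season EVI deviation (SD)",
      y = "Apparent annual survival",
      colour = "Wet-season EVI\ndeviation (SD)",
      fill = "Wet-season EVI\ndeviation (SD)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot Akaike weights of a model table
#'
#' @param object A `vg_model_table`.
#' @param top Show at most this many models.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vg_model_table
#' @export
autoplot.vg_model_table <- function(object, top = 16, ...) {
  d <- head(as_tibble(object), top)
  d$model <- factor(d$model, levels = rev(d$model))
  ggplot2::ggplot(d, ggplot2::aes(.data$weight, .data$model)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "AICc weight", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the rainfall-greenness relationship
#'
#' Scatter of EVI against rainfall with the fitted log-linear curve.
#'
#' @param object A `rain_evi_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rain_evi_fit
#' @export
autoplot.rain_evi_fit <- function(object, ...) {
  d <- object$fit$model
  names(d) <- c("evi", "log_rain")
  d$rain_mm <- exp(d$log_rain)
  curve <- tibble(rain_mm = seq(min(d$rain_mm), max(d$rain_mm), length.out = 200))
  curve$evi <- object$intercept + object$slope * log(curve$rain_mm)
  ggplot2::ggplot(d, ggplot2::aes(.data$rain_mm, .data$evi)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::labs(x = "Monthly rainfall (mm)", y = "EVI") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
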