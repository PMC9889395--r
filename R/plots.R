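#' Plot abundance time series per bag
#'
#' @param table A measurement tibble.
#' @param variables Variables to show (default all).
#' @return A ggplot object (log10 y scale, one facet per variable).
#' @export
plot_abundances <- function(table, variables = NULL) {
  x <- table
  if (!is.null(variables)) {
    x <- dplyr::filter(x, .data$variable %in% variables)
  }
  ggplot2::ggplot(dplyr::filter(x, .data$value > 0),
                  ggplot2::aes(x = .data$day, y = .data$value,
                               colour = factor(.data$bag))) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "day", y = "value", colour = "bag") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_production_model Observed vs fitted pool series and the
#'   loss-fraction scan.
#' @param object A `carbon_fit`.
#' @param ... Unused.
#' @export
autoplot.carbon_fit <- function(object, ...) {
  df <- dplyr::mutate(object$observed, fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(y = "pool",
                  title = sprintf("d = %.4f, R² = %.4f", object$d,
                                  object$r2)) +
    ggplot2::theme_minimal()
}

#' @describeIn cluster_succession Mean +/- sd normalized profile per
#'   cluster.
#' @param object A `cluster_result`.
#' @param ... Unused.
#' @export
autoplot.cluster_result <- function(object, ...) {
  ggplot2::ggplot(object$profiles,
                  ggplot2::aes(x = .data$day, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(y = "normalized abundance") +
    ggplot2::theme_minimal()
}

#' Plot a Bray-Curtis turnover curve with its fitted exponential decay
#'
#' @param comp A long composition tibble.
#' @param bag Bag to show.
#' @param start_day Reference day.
#' @param floor Similarity floor.
#' @return A ggplot object.
#' @export
plot_turnover <- function(comp, bag, start_day, floor = 0.05) {
  curve <- turnover_curve(comp, bag, start_day)
  fit <- fit_turnover(comp, bag, start_day, floor)
  curve$fitted <- (1 - floor) * exp(-fit$k * (curve$day - start_day)) +
    floor
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$day)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$similarity)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(y = "Bray-Curtis similarity",
                  title = sprintf("bag %s: k = %.3f /day", bag, fit$k)) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_infection_multiplier Deviation profile of the
#'   multiplier scan.
#' @param object An `infection_fit`.
#' @param ... Unused.
#' @export
autoplot.infection_fit <- function(object, ...) {
  ggplot2::ggplot(object$i_scan,
                  ggplot2::aes(x = .data$I, y = .data$deviation)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$I, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "infected-cell multiplier I",
                  y = "squared deviation") +
    ggplot2::theme_minimal()
}
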