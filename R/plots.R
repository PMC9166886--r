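#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot forecast fans for selected persons
#'
#' Forecast means with central interval ribbons per factor and horizon.
#'
#' @param object An [rsdfm_forecast()] result.
#' @param persons Persons to display (default: first 4).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rsdfm_forecast
#' @export
autoplot.rsdfm_forecast <- function(object, persons = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (is.null(persons)) persons <- utils::head(unique(df$person), 4)
  df <- df[df$person %in% persons, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$horizon, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$factor),
                        cols = ggplot2::vars(.data$person),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "forecast horizon", y = "latent factor score",
                  title = sprintf("%d%% forecast intervals",
                                  round(100 * attr(object, "level")))) +
    ggplot2::theme_minimal()
}

#' Trace plots of posterior draws
#'
#' @param object An [rsdfm_fit()] object.
#' @param parameters Parameter names to display (default: a small
#'   representative subset).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rsdfm_fit
#' @export
autoplot.rsdfm_fit <- function(object, parameters = NULL, ...) {
  if (is.null(parameters)) {
    parameters <- intersect(c("b1[1,1]", "delta_alpha21[1]", "gamma1", "p12"),
                            colnames(object$draws))
  }
  df <- tibble::tibble(
    chain = factor(rep(object$chain, times = length(parameters))),
    iteration = rep(object$iteration, times = length(parameters)),
    parameter = rep(parameters, each = nrow(object$draws)),
    value = as.vector(object$draws[, parameters, drop = FALSE]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value,
                                   colour = .data$chain)) +
    ggplot2::geom_line(linewidth = 0.2, alpha = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter), scales = "free_y") +
    ggplot2::labs(x = "kept iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Score-function and interval-width curves across horizons
#'
#' Line plots of the per-horizon quadratic score (`delta_h`) or mean
#' forecast-interval width by condition: the interval-width panel widens
#' with the horizon (megaphone shape).
#'
#' @param curves The `curves` element of [aggregate_table()] (columns
#'   `N1`, `Nt`, `horizon`, `delta_h`, `fi_width`).
#' @param metric `"delta_h"` or `"fi_width"`.
#' @return A ggplot object.
#' @export
plot_horizon_curves <- function(curves, metric = c("delta_h", "fi_width")) {
  metric <- match.arg(metric)
  curves$condition <- sprintf("N1=%d, Nt=%d", curves$N1, curves$Nt)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$horizon,
                                       y = .data[[metric]],
                                       colour = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "forecast horizon",
                  y = if (metric == "delta_h") "quadratic score" else
                    "mean forecast-interval width") +
    ggplot2::theme_minimal()
}

#' State-probability trajectories for selected persons
#'
#' Filtered probability of the elevated state over the observation window
#' followed by the forecast state probabilities.
#'
#' @param forecast An [rsdfm_forecast()] result.
#' @param persons Persons to display (default: first 3).
#' @return A ggplot object.
#' @export
plot_state_trajectories <- function(forecast, persons = NULL) {
  p2o <- attr(forecast, "p2_observed")
  d <- attr(forecast, "dims")
  if (is.null(persons)) persons <- seq_len(min(3, d$N1))
  fs <- forecast_states(forecast)
  obs <- tibble::tibble(
    person = rep(seq_len(d$N1), times = ncol(p2o)),
    occasion = rep(seq_len(ncol(p2o)), each = nrow(p2o)),
    p_state2 = as.vector(p2o), window = "observed")
  fore <- tibble::tibble(person = fs$person, occasion = d$Nt + fs$horizon,
                         p_state2 = fs$p_state2, window = "forecast")
  df <- dplyr::bind_rows(obs, fore)
  df <- df[df$person %in% persons, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$occasion, y = .data$p_state2,
                                   linetype = .data$window)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = d$Nt + 0.5, colour = "grey50",
                        linetype = "dotted") +
    ggplot2::facet_wrap(ggplot2::vars(.data$person), labeller = ggplot2::label_both) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "P(state 2)", x = "occasion") +
    ggplot2::theme_minimal()
}
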