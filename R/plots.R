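#' Plot an interface trace
#'
#' Time course of the interface fraction `alpha` and its linearizing
#' transform `beta` as stacked panels.
#'
#' @param object A `coflow_trace` tibble (from [simulate_linear()],
#'   [interface_trace()] or [gen_beta_trace()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coflow_trace
#' @export
autoplot.coflow_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), "time_s", dplyr::any_of(c("alpha", "beta"))),
    -"time_s", names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Co-flow interface trace") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.coflow_trace
#' @export
plot_interface_trace <- function(object, ...) autoplot.coflow_trace(object, ...)

#' Plot an exponential transient fit
#'
#' Overlays the fitted first-order relaxation on the windowed data.
#'
#' @param object A `coflow_expfit` from [fit_time_constant()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coflow_expfit
#' @export
autoplot.coflow_expfit <- function(object, ...) {
  d <- object$data
  tt <- seq(min(d$time_s), max(d$time_s), length.out = 200)
  curve <- tibble(time_s = tt,
                  y = object$beta0 + object$beta1 *
                    exp(-(tt - min(d$time_s)) / object$lambda))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$y)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::labs(x = "time (s)", y = object$y_col,
                  title = sprintf("Exponential fit: lambda = %.3g s", object$lambda)) +
    ggplot2::theme_minimal()
}

#' Plot per-period rheology results
#'
#' One panel per quantity (viscosity, time constants, elasticity,
#' aggregation index) across periods.
#'
#' @param object A `rheo_summary` from [analyze_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rheo_summary
#' @export
autoplot.rheo_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object),
                              c("mu_B_cP", "lambda_off_s", "lambda_on_s",
                                "G_B_mPa", "AI"),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$period, y = .data$value)) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "period", y = NULL,
                  title = "Per-period blood rheology") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.rheo_summary
#' @export
plot_rheo_summary <- function(object, ...) autoplot.rheo_summary(object, ...)

#' Plot a power-law viscosity fit
#'
#' Apparent viscosity against shear rate on log-log axes with the fitted
#' Ostwald-de Waele line.
#'
#' @param object A `coflow_powerlaw` from [power_law_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coflow_powerlaw
#' @export
autoplot.coflow_powerlaw <- function(object, ...) {
  d <- object$data
  gg <- exp(seq(log(min(d$gamma_dot)), log(max(d$gamma_dot)), length.out = 100))
  curve <- tibble(gamma_dot = gg, mu = object$mu0 * gg^(object$n - 1))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gamma_dot, y = .data$mu)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "shear rate (1/s)", y = "viscosity (cP)",
                  title = sprintf("Power law: mu0 = %.3g, n = %.3g",
                                  object$mu0, object$n)) +
    ggplot2::theme_minimal()
}
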