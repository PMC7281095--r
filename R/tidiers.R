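#' Tidy an exponential transient fit
#'
#' @param x A `coflow_expfit` from [fit_time_constant()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`,
#'   `std.error`).
#' @method tidy coflow_expfit
#' @export
tidy.coflow_expfit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = c("beta0", "beta1", "lambda"),
         estimate = c(x$beta0, x$beta1, x$lambda),
         std.error = unname(sm[, "Std. Error"]))
}

#' @rdname tidy.coflow_expfit
#' @method glance coflow_expfit
#' @export
glance.coflow_expfit <- function(x, ...) {
  tibble(beta0 = x$beta0, beta1 = x$beta1, lambda = x$lambda,
         rms_residual = x$rms_residual, n_points = x$n_points,
         window_start = x$window[1], window_end = x$window[2])
}

#' Tidy a power-law viscosity fit
#'
#' @param x A `coflow_powerlaw` from [power_law_fit()].
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` rows for `mu0` and `n`.
#' @method tidy coflow_powerlaw
#' @export
tidy.coflow_powerlaw <- function(x, ...) {
  tibble(term = c("mu0", "n"), estimate = c(x$mu0, x$n))
}

#' @rdname tidy.coflow_powerlaw
#' @method glance coflow_powerlaw
#' @export
glance.coflow_powerlaw <- function(x, ...) {
  tibble(mu0 = x$mu0, n = x$n, r.squared = x$r_squared,
         nobs = nrow(x$data))
}

#' Tidy per-period rheology results
#'
#' @param x A `rheo_summary` from [analyze_experiment()].
#' @param ... Unused.
#' @return [tidy()] returns the per-period tibble; [glance()] the
#'   mean +/- sd summary across periods.
#' @method tidy rheo_summary
#' @export
tidy.rheo_summary <- function(x, ...) {
  out <- x
  attributes(out)[c("summary", "varying_flow", "config")] <- NULL
  class(out) <- setdiff(class(out), "rheo_summary")
  as_tibble(out)
}

#' @rdname tidy.rheo_summary
#' @method glance rheo_summary
#' @export
glance.rheo_summary <- function(x, ...) {
  attr(x, "summary")
}

#' @rdname fit_velocity_calibration
#' @param x A `velocity_calibration`.
#' @param ... Unused.
#' @method glance velocity_calibration
#' @export
glance.velocity_calibration <- function(x, ...) {
  tibble(slope = x$slope, r.squared = x$r_squared, diluent = x$diluent)
}
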