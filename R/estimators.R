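#' Fit an exponential time constant to one pump transient
#'
#' After each pump transition the linearized circuit model predicts a
#' first-order relaxation `beta(t) = beta0 + beta1 * exp(-t/lambda)`. The
#' fit is damped (Levenberg-Marquardt) nonlinear least squares on the
#' requested window, with time measured from the window start.
#' Initialization: `beta0` = last sample, `beta1` = first - last,
#' `lambda` = window length / 5; `lambda` is bounded in
#' `(dt/10, 10 * window]`.
#'
#' @param trace A data frame with a time column and a response column
#'   (defaults `time_s`, `beta`).
#' @param window Numeric `c(start, end)` in the trace's time units; `NULL`
#'   uses the whole trace.
#' @param t_col,y_col Column names of time and response.
#' @return An object of class `coflow_expfit` with elements `beta0`,
#'   `beta1`, `lambda`, `rms_residual`, `window`, `n_points`. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' t <- seq(0, 60, 0.5)
#' fit <- fit_time_constant(tibble::tibble(time_s = t,
#'                                         beta = 2 + 1.5 * exp(-t / 10)))
#' glance(fit)$lambda
#' @export
fit_time_constant <- function(trace, window = NULL, t_col = "time_s",
                              y_col = "beta") {
  stopifnot(is.data.frame(trace), all(c(t_col, y_col) %in% names(trace)))
  t <- trace[[t_col]]; y <- trace[[y_col]]
  if (is.null(window)) window <- range(t)
  keep <- t >= window[1] - 1e-9 & t <= window[2] + 1e-9
  t <- t[keep]; y <- y[keep]
  if (length(t) < 4L) abort("at least 4 samples are required in the fit window.")
  ts <- t - t[1]
  win_len <- max(ts)
  dt <- median(diff(ts))

  b0 <- tail(y, 1)
  b1 <- y[1] - b0
  if (abs(b1) < 1e-3) {
    abort(sprintf(
      "degenerate fit: transient amplitude |first - last| = %.2g is below 1e-3.",
      abs(b1)))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ beta0 + beta1 * exp(-ts / lam),
      start = list(beta0 = b0, beta1 = b1, lam = win_len / 5),
      lower = c(-Inf, -Inf, dt / 10),
      upper = c(Inf, Inf, 10 * win_len),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) abort(paste0("exponential fit failed to converge: ",
                                     conditionMessage(e)))
  )
  cf <- coef(fit)
  structure(
    list(beta0 = unname(cf["beta0"]), beta1 = unname(cf["beta1"]),
         lambda = unname(cf["lam"]),
         rms_residual = sqrt(mean(residuals(fit)^2)),
         window = c(t[1], t[1] + win_len), n_points = length(ts),
         data = tibble(time_s = t, y = y), fit = fit,
         y_col = y_col),
    class = "coflow_expfit"
  )
}

#' @export
print.coflow_expfit <- function(x, ...) {
  cat(sprintf(
    "<coflow_expfit> y = %.5g + %.5g * exp(-t/%.5g), lambda = %.4g s\n  window [%g, %g] s, n = %d, rms residual = %.3g\n",
    x$beta0, x$beta1, x$lambda, x$lambda, x$window[1], x$window[2],
    x$n_points, x$rms_residual))
  invisible(x)
}

#' Viscosity from the steady interface at matched flow rates
#'
#' At steady state with `Q_T = Q_R`, inverting the linearized circuit model
#' gives `mu_B = mu_R * (beta - 1) * F2`.
#'
#' @param beta Steady-state interface variable (>= 1), typically the mean
#'   over a converged sub-window of the on segment.
#' @param mu_R Reference-fluid viscosity (cP).
#' @param constants A [model_constants()] object.
#' @return Viscosity in cP.
#' @examples
#' viscosity_constant_flow(3.61293, 1) # 2.95 cP
#' @export
viscosity_constant_flow <- function(beta, mu_R, constants = model_constants()) {
  if (any(beta < 1)) abort("`beta` must be >= 1.")
  check_positive(mu_R, "mu_R")
  mu <- mu_R * (beta - 1) * constants$F2
  if (any(beta == 1)) warn("beta = 1 gives zero viscosity (zero-width lane): nonphysical.")
  mu
}

#' Flow-corrected viscosity under a varying blood flow rate
#'
#' When the blood flow rate decays after pump stop, the steady-state
#' formula is corrected by the instantaneous flow ratio:
#' `mu_B(t) = mu_R * (beta - 1) * F2 * (Q_R / Q_B)`. Samples with
#' `Q_B < Q_min` are excluded (the correction diverges as the flow stalls).
#'
#' @param data A data frame with columns `time_s`, a beta column and a
#'   blood-flow column.
#' @param mu_R Reference viscosity (cP).
#' @param Q_R Reference flow rate (mL/h).
#' @param Q_min Exclusion threshold on `Q_B` (mL/h). Default 0.1.
#' @param beta_col,Q_col Column names (defaults `beta`, `Q_B_mLh`).
#' @param constants A [model_constants()] object.
#' @return A tibble `time_s`, `Q_B_mLh`, `mu_B_cP` restricted to
#'   `Q_B >= Q_min`.
#' @export
viscosity_varying_flow <- function(data, mu_R, Q_R, Q_min = 0.1,
                                   beta_col = "beta", Q_col = "Q_B_mLh",
                                   constants = model_constants()) {
  stopifnot(is.data.frame(data), all(c("time_s", beta_col, Q_col) %in% names(data)))
  check_positive(mu_R, "mu_R"); check_positive(Q_R, "Q_R")
  keep <- data[[Q_col]] >= Q_min
  if (!any(keep)) abort(sprintf("no samples with Q_B >= Q_min = %g mL/h.", Q_min))
  d <- data[keep, , drop = FALSE]
  tibble(
    time_s = d$time_s,
    Q_B_mLh = d[[Q_col]],
    mu_B_cP = mu_R * (d[[beta_col]] - 1) * constants$F2 * (Q_R / d[[Q_col]])
  )
}

#' Characteristic wall shear rate of a shallow rectangular channel
#'
#' `gamma_dot = 6 Q / (W h^2)`, the low-aspect-ratio approximation.
#'
#' @param Q Flow rate (mL/h); may be a vector.
#' @param geom A [channel_geometry()] object.
#' @return Shear rate in 1/s.
#' @examples
#' shear_rate(0.5, channel_geometry()) # 83.33 1/s
#' @export
shear_rate <- function(Q, geom = channel_geometry()) {
  stopifnot(inherits(geom, "channel_geometry"))
  if (any(Q < 0)) abort("`Q` must be >= 0.")
  6 * mlh_to_m3s(Q) / (um_to_m(geom$W) * um_to_m(geom$h)^2)
}

#' Equivalent circular diameter of a filled rectangular cross-section
#'
#' `d = sqrt(4 * W_fill * h / pi)` by area conservation; `W_fill` is the
#' filled width (`alpha * W` for the blood lane of a co-flow channel, `W`
#' for a fully filled channel).
#'
#' @param W_fill Filled width (um).
#' @param h Channel depth (um).
#' @return Diameter in um.
#' @examples
#' equivalent_diameter(650, 100) # ~288 um
#' @export
equivalent_diameter <- function(W_fill, h) {
  if (any(W_fill <= 0) || any(h <= 0)) abort("dimensions must be positive.")
  sqrt(4 * W_fill * h / pi)
}

#' Maxwell elastic modulus from viscosity and relaxation time
#'
#' The linear Maxwell model links the relaxation time to viscosity and
#' elasticity via `lambda = mu / G`, so `G_B = mu_B / lambda`. Reported in
#' mPa (`mu` in cP is converted to Pa s before dividing).
#'
#' @param mu_B Viscosity (cP).
#' @param lam Relaxation time constant (s).
#' @return Elastic modulus in mPa.
#' @examples
#' elasticity(2.95, 5.9) # 0.5 mPa
#' @export
elasticity <- function(mu_B, lam) {
  if (any(lam <= 0)) abort("`lam` must be positive.")
  cp_to_pas(mu_B) / lam * 1e3
}

#' Post-stop intensity minimum
#'
#' Finds `t0`, the time of the minimum ROI-averaged intensity within a
#' window after pump stop (ties broken by the earliest time). RBC
#' aggregation then raises the intensity from this minimum.
#'
#' @param intensity A data frame with columns `time_s`, `I_mean`.
#' @param window `c(start, end)` in seconds; `NULL` uses the whole trace.
#' @return `t0` in seconds.
#' @export
find_t0 <- function(intensity, window = NULL) {
  stopifnot(is.data.frame(intensity),
            all(c("time_s", "I_mean") %in% names(intensity)))
  t <- intensity$time_s; I <- intensity$I_mean
  if (!is.null(window)) {
    keep <- t >= window[1] - 1e-9 & t <= window[2] + 1e-9
    t <- t[keep]; I <- I[keep]
  }
  if (!length(t)) abort("empty intensity window.")
  t[which.min(I)]
}

#' RBC aggregation index
#'
#' Time-normalized integral of the intensity rise above its post-stop
#' minimum: `AI = (1/ts) * integral over [t0, t0 + ts] of
#' (I(t) - I(t0)) dt`, evaluated by the trapezoid rule on the sampling
#' grid. Signed values are integrated as-is.
#'
#' @param intensity A data frame with columns `time_s`, `I_mean`.
#' @param t0 Start of the integration span (s), typically from [find_t0()].
#' @param ts Integration span (s).
#' @return An object of class `aggregation_result` with elements `t0`,
#'   `ts`, `AI` (gray-level units).
#' @export
aggregation_index <- function(intensity, t0, ts) {
  stopifnot(is.data.frame(intensity),
            all(c("time_s", "I_mean") %in% names(intensity)))
  check_positive(ts, "ts")
  t <- intensity$time_s
  if (t0 < t[1] - 1e-9 || t0 + ts > tail(t, 1) + 1e-9) {
    abort(sprintf("integration span [%g, %g] s exceeds the trace [%g, %g] s.",
                  t0, t0 + ts, t[1], tail(t, 1)))
  }
  keep <- t >= t0 - 1e-9 & t <= t0 + ts + 1e-9
  tt <- t[keep]
  ii <- intensity$I_mean[keep] - intensity$I_mean[keep][1]
  integral <- sum(diff(tt) * (head(ii, -1) + tail(ii, -1)) / 2)
  structure(list(t0 = t0, ts = ts, AI = integral / ts),
            class = "aggregation_result")
}

#' @export
print.aggregation_result <- function(x, ...) {
  cat(sprintf("<aggregation_result> AI = %.4g (gray levels), t0 = %g s, span = %g s\n",
              x$AI, x$t0, x$ts))
  invisible(x)
}

#' Fit the velocity-to-flow calibration
#'
#' The ROI-averaged velocity grows linearly with the set flow rate; the
#' calibration is a through-origin regression `U = slope * Q` whose slope
#' converts velocities back to flow rates.
#'
#' @param data A data frame with a flow column and a velocity column.
#' @param Q_col,U_col Column names (defaults `Q_mLh`, `U_mms`).
#' @param diluent Optional label.
#' @return An object of class `velocity_calibration` with `slope`
#'   ((mm/s)/(mL/h)), `r_squared` and `diluent`.
#' @export
fit_velocity_calibration <- function(data, Q_col = "Q_mLh", U_col = "U_mms",
                                     diluent = NA_character_) {
  stopifnot(is.data.frame(data), all(c(Q_col, U_col) %in% names(data)))
  m <- lm(data[[U_col]] ~ 0 + data[[Q_col]])
  slope <- unname(coef(m)[1])
  if (!is.finite(slope) || slope <= 0) abort("calibration slope must be positive.")
  ss_res <- sum(residuals(m)^2)
  ss_tot <- sum((data[[U_col]] - mean(data[[U_col]]))^2)
  structure(list(slope = slope,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 diluent = diluent),
            class = "velocity_calibration")
}

#' @rdname fit_velocity_calibration
#' @param slope Calibration slope ((mm/s)/(mL/h)).
#' @export
velocity_calibration <- function(slope, diluent = NA_character_,
                                 r_squared = NA_real_) {
  check_positive(slope, "slope")
  structure(list(slope = slope, r_squared = r_squared, diluent = diluent),
            class = "velocity_calibration")
}

#' @export
print.velocity_calibration <- function(x, ...) {
  cat(sprintf("<velocity_calibration> U = %.4f * Q (mm/s per mL/h)%s%s\n",
              x$slope,
              if (!is.na(x$r_squared)) sprintf(", R^2 = %.4f", x$r_squared) else "",
              if (!is.na(x$diluent)) paste0(", ", x$diluent) else ""))
  invisible(x)
}

#' Convert a velocity trace to a blood flow-rate trace
#'
#' Inverts the linear calibration elementwise: `Q_B = U / slope`.
#'
#' @param data A data frame with columns `time_s` and a velocity column
#'   (`U_mms` by default).
#' @param calib A [velocity_calibration()] (or a bare positive slope).
#' @param U_col Velocity column name.
#' @return The input tibble with an added `Q_B_mLh` column.
#' @export
velocity_to_flow <- function(data, calib, U_col = "U_mms") {
  stopifnot(is.data.frame(data), U_col %in% names(data))
  slope <- if (inherits(calib, "velocity_calibration")) calib$slope else calib
  check_positive(slope, "slope")
  dplyr::mutate(as_tibble(data), Q_B_mLh = .data[[U_col]] / slope)
}

#' Power-law (Ostwald-de Waele) viscosity summary
#'
#' Fits the apparent-viscosity form `mu(gamma_dot) = mu0 * gamma_dot^(n-1)`
#' by least squares in log-log space. `n = 1` recovers a Newtonian fluid;
#' `n < 1` is shear-thinning.
#'
#' @param data A data frame with a shear-rate column and a viscosity column.
#' @param gamma_col,mu_col Column names (defaults `gamma_dot`, `mu_cP`).
#' @return An object of class `coflow_powerlaw` with `mu0`, `n`,
#'   `r_squared`. Supports [tidy()] and [glance()].
#' @export
power_law_fit <- function(data, gamma_col = "gamma_dot", mu_col = "mu_cP") {
  stopifnot(is.data.frame(data), all(c(gamma_col, mu_col) %in% names(data)))
  g <- data[[gamma_col]]; mu <- data[[mu_col]]
  if (length(g) < 3L) abort("at least 3 (shear rate, viscosity) pairs are required.")
  if (any(g <= 0) || any(mu <= 0)) abort("shear rates and viscosities must be positive.")
  m <- lm(log(mu) ~ log(g))
  cf <- coef(m)
  ss_res <- sum(residuals(m)^2)
  ss_tot <- sum((log(mu) - mean(log(mu)))^2)
  structure(
    list(mu0 = exp(unname(cf[1])), n = unname(cf[2]) + 1,
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
         fit = m, data = tibble(gamma_dot = g, mu = mu)),
    class = "coflow_powerlaw"
  )
}

#' @export
print.coflow_powerlaw <- function(x, ...) {
  cat(sprintf("<coflow_powerlaw> mu = %.4g * gamma_dot^(%.4g - 1), R^2 = %.4f\n",
              x$mu0, x$n, x$r_squared))
  invisible(x)
}
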