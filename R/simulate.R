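#' Steady-state interface position of the linearized model
#'
#' Setting `d beta/dt = 0` in the linearized circuit model gives
#' `beta_ss = 1 + (1/F2) * (Q_T/Q_R) * (mu_T/mu_R)`; the companion
#' `steady_state_alpha()` returns `1 - 1/beta_ss`.
#'
#' @param Q_T,Q_R Test and reference flow rates (same units; only the ratio
#'   enters). `Q_R` must be positive.
#' @param mu_T,mu_R Test and reference viscosities (same units).
#' @param constants A [model_constants()] object.
#' @return Steady-state `beta` (or `alpha`).
#' @examples
#' steady_state_beta(1, 1, 2.95, 1) # 3.61293
#' @export
steady_state_beta <- function(Q_T, Q_R, mu_T, mu_R,
                              constants = model_constants()) {
  if (any(Q_R <= 0)) abort("`Q_R` must be positive.")
  if (any(Q_T < 0)) abort("`Q_T` must be >= 0.")
  check_positive(mu_T, "mu_T"); check_positive(mu_R, "mu_R")
  1 + (1 / constants$F2) * (Q_T / Q_R) * (mu_T / mu_R)
}

#' @rdname steady_state_beta
#' @export
steady_state_alpha <- function(Q_T, Q_R, mu_T, mu_R,
                               constants = model_constants()) {
  1 - 1 / steady_state_beta(Q_T, Q_R, mu_T, mu_R, constants)
}

#' Steady-state interface of the nonlinear model
#'
#' Solves `C_f(alpha) * alpha / (1 - alpha) = (Q_T/Q_R) * (mu_T/mu_R)` for
#' `alpha` by monotone bracketing on the validity interval of the
#' correction polynomial.
#'
#' @inheritParams steady_state_beta
#' @return Steady-state `alpha`.
#' @export
steady_state_alpha_nonlinear <- function(Q_T, Q_R, mu_T, mu_R,
                                         constants = model_constants()) {
  if (Q_R <= 0) abort("`Q_R` must be positive.")
  rhs <- (Q_T / Q_R) * (mu_T / mu_R)
  rng <- constants$cf_alpha_range
  f <- function(a) cf_eval(a, constants$cf_coeffs) * a / (1 - a) - rhs
  lo <- rng[1] + 1e-9; hi <- rng[2] - 1e-9
  if (f(lo) > 0 || f(hi) < 0) {
    abort("nonlinear steady state falls outside the correction-factor validity range.")
  }
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}

## Per-segment schedule of the on-off protocol: start/end times, the test
## flow during the segment and which time constant applies.
protocol_segments <- function(protocol) {
  T_ <- protocol$period_s
  on_len <- protocol$duty * T_
  k <- seq_len(protocol$n_periods)
  tibble(
    period = rep(k, each = 2L),
    phase = rep(c("on", "off"), protocol$n_periods),
    t_start = as.vector(rbind((k - 1) * T_, (k - 1) * T_ + on_len)),
    t_end = as.vector(rbind((k - 1) * T_ + on_len, k * T_)),
    Q_T = rep(c(protocol$Q_T_on, 0), protocol$n_periods)
  )
}

#' Simulate the linearized co-flow circuit under a periodic pump protocol
#'
#' Integrates `lambda * d beta/dt + beta = 1 + (1/F2)(Q_T/Q_R)(mu_T/mu_R)`
#' piecewise over the on/off segments of the protocol. Pump switching is an
#' instantaneous step in `Q_T`; `lambda_on` applies while the test pump is
#' on and `lambda_off` while it is off. Integration uses adaptive `lsoda`
#' with relative tolerance 1e-8, reported on the protocol sampling grid.
#'
#' @param protocol A [pump_protocol()] object.
#' @param compliance A [compliance_pack()] object.
#' @param fluids A [fluid_pair()] object.
#' @param beta_init Initial `beta` (>= 1). Default 1 (no test fluid).
#' @param constants A [model_constants()] object.
#' @return A tibble of class `coflow_trace` with columns `time_s`,
#'   `Q_T_mLh`, `Q_R_mLh`, `alpha`, `beta`.
#' @examples
#' tr <- simulate_linear(pump_protocol(n_periods = 1),
#'                       compliance_pack(3.2, 5.9), fluid_pair(1, 2.95))
#' head(tr)
#' @export
simulate_linear <- function(protocol, compliance, fluids, beta_init = 1,
                            constants = model_constants()) {
  stopifnot(inherits(protocol, "pump_protocol"),
            inherits(compliance, "compliance_pack"),
            inherits(fluids, "fluid_pair"))
  if (beta_init < 1) abort("`beta_init` must be >= 1 (alpha would be negative).")

  segs <- protocol_segments(protocol)
  dt <- protocol$dt
  grid <- seq(0, protocol$n_periods * protocol$period_s, by = dt)

  beta <- numeric(length(grid))
  qt <- numeric(length(grid))
  state <- beta_init
  for (i in seq_len(nrow(segs))) {
    lam <- if (segs$phase[i] == "on") compliance$lambda_on else compliance$lambda_off
    bss <- steady_state_beta(segs$Q_T[i], protocol$Q_R,
                             fluids$mu_T, fluids$mu_R, constants)
    idx <- which(grid >= segs$t_start[i] - 1e-9 & grid <= segs$t_end[i] + 1e-9)
    times <- grid[idx] - segs$t_start[i]
    if (times[1] > 1e-12) times <- c(0, times)
    sol <- deSolve::ode(
      y = c(beta = state), times = times,
      func = function(t, y, p) list((bss - y) / lam),
      parms = NULL, method = "lsoda", rtol = 1e-8, atol = 1e-10
    )
    vals <- sol[, "beta"]
    if (length(vals) > length(idx)) vals <- vals[-1]
    beta[idx] <- vals
    qt[idx] <- segs$Q_T[i]
    state <- tail(vals, 1)
  }
  ## samples at switch instants take the incoming segment's flow
  on_starts <- segs$t_start[segs$phase == "on"]
  qt[grid %in% on_starts] <- protocol$Q_T_on

  new_coflow_trace(tibble(
    time_s = grid, Q_T_mLh = qt, Q_R_mLh = protocol$Q_R,
    alpha = 1 - 1 / beta, beta = beta
  ))
}

#' Simulate the nonlinear co-flow circuit model
#'
#' Integrates the nonlinear governing equation
#' `C_T * R_WT * d/dt(C_f/(1 - alpha)) + C_f * alpha/(1 - alpha) =
#' (Q_T/Q_R)(mu_T/mu_R)` by treating `y = C_f(alpha)/(1 - alpha)` as the
#' state variable and inverting `y -> alpha` by monotone bracketing on the
#' validity interval of the correction polynomial.
#'
#' @inheritParams simulate_linear
#' @param geom A [channel_geometry()] object (used with `C_T`).
#' @param C_T Compliance (uL/Pa). Either `C_T` (with `geom`) or `tau_s`
#'   must be given.
#' @param tau_s Directly specified relaxation scale `C_T * R_WT` (s),
#'   bypassing the geometry.
#' @param alpha_init Initial interface fraction, within the validity range.
#' @return A `coflow_trace` tibble with columns `time_s`, `Q_T_mLh`,
#'   `Q_R_mLh`, `alpha`, `beta`.
#' @export
simulate_nonlinear <- function(protocol, geom = channel_geometry(),
                               fluids = fluid_pair(), C_T = NULL,
                               tau_s = NULL, alpha_init = 0.15,
                               constants = model_constants()) {
  stopifnot(inherits(protocol, "pump_protocol"), inherits(fluids, "fluid_pair"))
  rng <- constants$cf_alpha_range
  if (alpha_init <= rng[1] || alpha_init >= rng[2]) {
    abort("`alpha_init` must lie inside the correction-factor validity range.")
  }
  if (is.null(tau_s)) {
    if (is.null(C_T)) abort("provide either `C_T` (with `geom`) or `tau_s`.")
    tau_s <- ul_per_pa_to_si(C_T) * lane_resistance(geom, fluids$mu_T)
  }
  check_positive(tau_s, "tau_s")

  coeffs <- constants$cf_coeffs
  y_of_alpha <- function(a) cf_eval(a, coeffs) / (1 - a)
  ## The fitted quartic makes y(alpha) non-monotone near the lower end of
  ## the validity interval (a shallow minimum near alpha ~ 0.2 with the
  ## default coefficients); the state is only invertible on the increasing
  ## branch, which is the usable domain of the nonlinear simulator.
  opt <- optimize(y_of_alpha, rng)
  lo <- if (y_of_alpha(rng[1]) <= opt$objective + 1e-12) rng[1] else opt$minimum
  hi <- rng[2] - 1e-9
  y_lo <- y_of_alpha(lo); y_hi <- y_of_alpha(hi)
  if (alpha_init < lo) {
    abort(sprintf(
      "`alpha_init` = %g is below the invertible branch of the state transform; usable interval is (%.3f, %g).",
      alpha_init, lo, rng[2]))
  }
  alpha_of_y <- function(y, t) {
    if (y < y_lo - 1e-9 || y > y_hi + 1e-9) {
      abort(sprintf(
        "alpha left the usable interval (%.3f, %g) of the nonlinear model at t = %.3f s.",
        lo, rng[2], t))
    }
    y <- min(max(y, y_lo), y_hi)
    uniroot(function(a) y_of_alpha(a) - y, c(lo, hi), tol = 1e-12)$root
  }

  segs <- protocol_segments(protocol)
  dt <- protocol$dt
  grid <- seq(0, protocol$n_periods * protocol$period_s, by = dt)
  alpha <- numeric(length(grid))
  qt <- numeric(length(grid))
  y_state <- y_of_alpha(alpha_init)
  for (i in seq_len(nrow(segs))) {
    rhs <- (segs$Q_T[i] / protocol$Q_R) * (fluids$mu_T / fluids$mu_R)
    idx <- which(grid >= segs$t_start[i] - 1e-9 & grid <= segs$t_end[i] + 1e-9)
    times <- grid[idx] - segs$t_start[i]
    if (times[1] > 1e-12) times <- c(0, times)
    t0 <- segs$t_start[i]
    sol <- deSolve::ode(
      y = c(y = y_state), times = times,
      func = function(t, y, p) {
        a <- alpha_of_y(y[1], t0 + t)
        list((rhs - cf_eval(a, coeffs) * a / (1 - a)) / tau_s)
      },
      parms = NULL, method = "lsoda", rtol = 1e-8, atol = 1e-10
    )
    vals <- sol[, "y"]
    if (length(vals) > length(idx)) vals <- vals[-1]
    alpha[idx] <- vapply(seq_along(idx),
                         function(j) alpha_of_y(vals[j], grid[idx[j]]),
                         numeric(1))
    qt[idx] <- segs$Q_T[i]
    y_state <- tail(vals, 1)
  }
  on_starts <- segs$t_start[segs$phase == "on"]
  qt[grid %in% on_starts] <- protocol$Q_T_on

  new_coflow_trace(tibble(
    time_s = grid, Q_T_mLh = qt, Q_R_mLh = protocol$Q_R,
    alpha = alpha, beta = 1 / (1 - alpha)
  ))
}

new_coflow_trace <- function(df) {
  class(df) <- c("coflow_trace", class(df))
  df
}
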