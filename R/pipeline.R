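#' Segment a trace into per-period analysis windows
#'
#' From the pump protocol, derives for each full period the on window, the
#' off window and the steady sub-window of the on segment used for the
#' constant-flow viscosity (by default its last 25%, ending at the on-to-off
#' transition).
#'
#' @param protocol A [pump_protocol()].
#' @param trace_length_s Length of the available trace (s); alternatively
#'   pass a data frame with a `time_s` column.
#' @param steady_frac Fraction of the on segment used as the steady
#'   sub-window. Default 0.25.
#' @return A tibble with one row per full period: `period`, `on_start`,
#'   `on_end`, `off_start`, `off_end`, `steady_start`, `steady_end` (s).
#' @export
segment_periods <- function(protocol, trace_length_s, steady_frac = 0.25) {
  stopifnot(inherits(protocol, "pump_protocol"))
  if (is.data.frame(trace_length_s)) {
    trace_length_s <- max(trace_length_s$time_s)
  }
  T_ <- protocol$period_s
  n_full <- floor(trace_length_s / T_ + 1e-9)
  if (n_full < 1) abort("trace shorter than one protocol period.")
  if (trace_length_s - n_full * T_ > protocol$dt / 2) {
    warn(sprintf("trace covers %d full period(s); the partial period beyond %g s is ignored.",
                 n_full, n_full * T_))
  }
  on_len <- protocol$duty * T_
  k <- seq_len(n_full)
  tibble(
    period = k,
    on_start = (k - 1) * T_,
    on_end = (k - 1) * T_ + on_len,
    off_start = (k - 1) * T_ + on_len,
    off_end = k * T_,
    steady_start = (k - 1) * T_ + on_len * (1 - steady_frac),
    steady_end = (k - 1) * T_ + on_len
  )
}

#' Convergence check for a steady sub-window
#'
#' The interface has converged when the relative drift across the
#' sub-window, `|beta_end - beta_start| / |beta_end|`, does not exceed
#' `tol`. Viscosity must not be read from a non-converged window (long
#' transients from air compliance leave `beta` still rising at the end of
#' the on half-period).
#'
#' To keep the flag stable under sampling noise, the endpoints are taken as
#' the means of the leading and trailing 20% of the sub-window (single
#' samples when the segment is short).
#'
#' @param beta Numeric vector of `beta` samples over the sub-window (or a
#'   data frame with a `beta` column).
#' @param tol Relative drift tolerance. Default 0.01.
#' @return Logical flag.
#' @export
check_convergence <- function(beta, tol = 0.01) {
  if (is.data.frame(beta)) beta <- beta$beta
  if (!length(beta)) abort("empty beta segment.")
  k <- max(1L, floor(length(beta) * 0.2))
  b_start <- mean(head(beta, k))
  b_end <- mean(tail(beta, k))
  drift <- abs(b_end - b_start) / abs(b_end)
  drift <= tol
}

#' Recommended protocol period for a given transient response
#'
#' A half-period must accommodate both the steady-measurement window and
#' the transient: the planner recommends `T >= 2 * (t_steady + 2 *
#' lambda_off)`. The companion helper returns the minimum half-period
#' extension needed to absorb a set of time-constant increments (their
#' maximum).
#'
#' @param t_steady_s Steady measurement window required (s).
#' @param lambda_off Off time constant (s).
#' @return Recommended minimum period (s).
#' @export
recommend_period <- function(t_steady_s, lambda_off) {
  check_positive(t_steady_s, "t_steady_s"); check_positive(lambda_off, "lambda_off")
  2 * (t_steady_s + 2 * lambda_off)
}

#' @rdname recommend_period
#' @param delta_lambda_off Time-constant increments (s) across conditions.
#' @export
recommend_half_period_extension <- function(delta_lambda_off) {
  if (!length(delta_lambda_off) || any(delta_lambda_off < 0)) {
    abort("`delta_lambda_off` must be nonnegative increments.")
  }
  max(delta_lambda_off)
}

## centered rolling mean used to stabilize the t0 search on noisy traces
roll_mean <- function(x, k) {
  if (k <= 1L) return(x)
  k <- min(k + (1 - k %% 2), length(x))  # force odd
  sm <- stats::filter(x, rep(1 / k, k), sides = 2)
  out <- as.numeric(sm)
  out[is.na(out)] <- x[is.na(out)]
  out
}

#' Per-period rheological analysis of a co-flow experiment
#'
#' Sequences the measurement chain exactly as acquired: per period, the
#' blood viscosity from the mean `beta` over the converged steady
#' sub-window of the on segment; the off and on time constants from
#' exponential fits over fixed windows after each transition (defaults 60 s
#' and 20 s); the Maxwell elasticity `G_B = mu_B / lambda_off`; and the
#' aggregation index from the intensity minimum after pump stop. A
#' varying-flow viscosity branch runs when a velocity trace and calibration
#' are supplied. Stage failures are recorded per period; the run fails only
#' if every period fails every stage.
#'
#' @param beta_trace A data frame with columns `time_s`, `beta`.
#' @param config A list: `protocol` ([pump_protocol()]), `mu_R` (cP,
#'   required), optional `constants`, `off_fit_window_s` (60),
#'   `on_fit_window_s` (20), `ts` (60), `steady_frac` (0.25), `conv_tol`
#'   (0.01), `t0_smooth_samples` (5), `Q_min` (0.1), `calibration`
#'   ([velocity_calibration()]).
#' @param intensity Optional intensity trace (`time_s`, `I_mean`).
#' @param velocity Optional velocity trace (`time_s`, `U_mms`).
#' @return An object of class `rheo_summary`: a tibble with one row per
#'   period (`period`, `mu_B_cP`, `lambda_off_s`, `lambda_on_s`, `G_B_mPa`,
#'   `AI`, `converged`, `note`) carrying the mean +/- sd summary as the
#'   `summary` attribute (also via [glance()]).
#' @export
analyze_experiment <- function(beta_trace, config, intensity = NULL,
                               velocity = NULL) {
  stopifnot(is.data.frame(beta_trace),
            all(c("time_s", "beta") %in% names(beta_trace)))
  if (is.null(config$protocol) || !inherits(config$protocol, "pump_protocol")) {
    abort("`config$protocol` must be a pump_protocol.")
  }
  if (is.null(config$mu_R)) abort("`config$mu_R` (reference viscosity, cP) is required.")
  constants <- config$constants %||% model_constants()
  off_win <- config$off_fit_window_s %||% 60
  on_win <- config$on_fit_window_s %||% 20
  ts <- config$ts %||% 60
  steady_frac <- config$steady_frac %||% 0.25
  conv_tol <- config$conv_tol %||% 0.01
  smooth_k <- config$t0_smooth_samples %||% 5L

  segs <- segment_periods(config$protocol, max(beta_trace$time_s),
                          steady_frac = steady_frac)
  t <- beta_trace$time_s

  int_sm <- NULL
  if (!is.null(intensity)) {
    int_sm <- intensity
    int_sm$I_mean <- roll_mean(intensity$I_mean, smooth_k)
  }

  rows <- purrr::map_dfr(seq_len(nrow(segs)), function(i) {
    s <- segs[i, ]
    note <- character(0)

    ## -- viscosity from the steady on sub-window (constant flow) --
    steady <- beta_trace[t >= s$steady_start - 1e-9 & t <= s$steady_end + 1e-9, ]
    converged <- tryCatch(check_convergence(steady$beta, conv_tol),
                          error = function(e) FALSE)
    mu_B <- NA_real_
    if (nrow(steady) && converged) {
      mu_B <- tryCatch(viscosity_constant_flow(mean(steady$beta), config$mu_R,
                                               constants),
                       error = function(e) { note <<- c(note, conditionMessage(e)); NA_real_ })
    } else {
      note <- c(note, sprintf(
        "period %d: steady sub-window not converged (relative beta drift > %g); mu_B omitted.",
        s$period, conv_tol))
      warn(tail(note, 1))
    }

    ## -- off time constant --
    lam_off <- tryCatch({
      fit <- fit_time_constant(beta_trace,
                               window = c(s$off_start, min(s$off_start + off_win, s$off_end)))
      fit$lambda
    }, error = function(e) { note <<- c(note, conditionMessage(e)); NA_real_ })

    ## -- on time constant --
    lam_on <- tryCatch({
      fit <- fit_time_constant(beta_trace,
                               window = c(s$on_start, min(s$on_start + on_win, s$on_end)))
      fit$lambda
    }, error = function(e) { note <<- c(note, conditionMessage(e)); NA_real_ })

    g_b <- if (!is.na(mu_B) && !is.na(lam_off)) elasticity(mu_B, lam_off) else NA_real_

    ## -- aggregation index from the intensity minimum after pump stop --
    ai <- NA_real_
    if (!is.null(intensity)) {
      ai <- tryCatch({
        ## locate the minimum on the smoothed trace, then refine it on the
        ## raw trace within one smoothing window (the rolling mean shifts
        ## the argmin when the rise is one-sided)
        t0_coarse <- find_t0(int_sm, window = c(s$off_start, s$off_end))
        half_w <- smooth_k * (config$protocol$dt %||% 0.5)
        t0 <- find_t0(intensity,
                      window = c(max(s$off_start, t0_coarse - half_w),
                                 min(s$off_end, t0_coarse + half_w)))
        aggregation_index(intensity, t0, ts)$AI
      }, error = function(e) { note <<- c(note, conditionMessage(e)); NA_real_ })
    }

    tibble(period = s$period, mu_B_cP = mu_B, lambda_off_s = lam_off,
           lambda_on_s = lam_on, G_B_mPa = g_b, AI = ai,
           converged = converged,
           note = paste(note, collapse = " | "))
  })

  if (all(is.na(rows$mu_B_cP)) && all(is.na(rows$lambda_off_s)) &&
      all(is.na(rows$AI))) {
    abort("analysis failed for every period; see the per-period notes.")
  }

  varying <- NULL
  if (!is.null(velocity) && !is.null(config$calibration)) {
    q <- velocity_to_flow(velocity, config$calibration)
    merged <- dplyr::inner_join(beta_trace, q, by = "time_s")
    varying <- tryCatch(
      viscosity_varying_flow(merged, config$mu_R, config$protocol$Q_R,
                             Q_min = config$Q_min %||% 0.1,
                             constants = constants),
      error = function(e) { warn(conditionMessage(e)); NULL })
  }

  summ <- rows |>
    dplyr::summarise(dplyr::across(
      c("mu_B_cP", "lambda_off_s", "lambda_on_s", "G_B_mPa", "AI"),
      list(mean = ~mean(.x, na.rm = TRUE), sd = ~sd(.x, na.rm = TRUE))))

  structure(rows, class = c("rheo_summary", class(rows)),
            summary = summ, varying_flow = varying,
            config = list(mu_R = config$mu_R, off_fit_window_s = off_win,
                          on_fit_window_s = on_win, ts = ts,
                          steady_frac = steady_frac, conv_tol = conv_tol,
                          t0_smooth_samples = smooth_k))
}

#' @export
print.rheo_summary <- function(x, ...) {
  cat("<rheo_summary> per-period blood rheology\n")
  NextMethod()
  s <- attr(x, "summary")
  cat(sprintf("mean +/- sd: mu_B = %.3g +/- %.2g cP, lambda_off = %.3g +/- %.2g s, G_B = %.3g +/- %.2g mPa, AI = %.3g +/- %.2g\n",
              s$mu_B_cP_mean, s$mu_B_cP_sd, s$lambda_off_s_mean,
              s$lambda_off_s_sd, s$G_B_mPa_mean, s$G_B_mPa_sd,
              s$AI_mean, s$AI_sd))
  invisible(x)
}
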