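#' Synthetic experiment scenario
#'
#' Bundles everything needed to emulate one co-flow experiment: the pump
#' protocol, the transient response (time constants), the fluid pair, the
#' aggregation kinetics of the intensity signal, the velocity calibration
#' and per-channel Gaussian noise levels. All generators are deterministic
#' given the scenario (the seed is mandatory).
#'
#' Aggregation is modelled phenomenologically: once the blood velocity
#' falls below `u_gate_mms` after pump stop, the ROI intensity rises from
#' its minimum as `A * (1 - exp(-(t - t_gate)/tau_agg))`. While flow
#' persists the intensity relaxes quickly (time scale `tau_disperse_s`)
#' toward the flowing baseline, which sits `dip_gray` below the pump-on
#' baseline during the decaying-flow phase so the post-stop minimum is well
#' defined.
#'
#' @param seed Integer seed (mandatory).
#' @param protocol A [pump_protocol()].
#' @param compliance A [compliance_pack()].
#' @param fluids A [fluid_pair()].
#' @param aggregation List with `amplitude` (gray levels), `tau_agg_s`,
#'   `u_gate_mms`, `dip_gray`, `tau_disperse_s`, `I_base`.
#' @param calibration_slope Velocity calibration ((mm/s)/(mL/h)).
#' @param noise List with `beta_rel` (sd relative to the segment
#'   amplitude), `intensity` (gray), `velocity_mms`, `image_gray`
#'   (per-pixel sd).
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed,
                               protocol = pump_protocol(),
                               compliance = compliance_pack(),
                               fluids = fluid_pair(),
                               aggregation = list(amplitude = 10, tau_agg_s = 20,
                                                  u_gate_mms = 0.2, dip_gray = 2,
                                                  tau_disperse_s = 2, I_base = 80),
                               calibration_slope = 2.0732,
                               noise = list(beta_rel = 0.01, intensity = 0.1,
                                            velocity_mms = 0.02, image_gray = 5)) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    abort("`seed` is mandatory and must be a single integer.")
  }
  agg_defaults <- list(amplitude = 10, tau_agg_s = 20, u_gate_mms = 0.2,
                       dip_gray = 2, tau_disperse_s = 2, I_base = 80)
  noise_defaults <- list(beta_rel = 0.01, intensity = 0.1,
                         velocity_mms = 0.02, image_gray = 5)
  aggregation <- utils::modifyList(agg_defaults, aggregation)
  noise <- utils::modifyList(noise_defaults, noise)
  if (aggregation$amplitude < 0) abort("aggregation amplitude must be >= 0.")
  if (any(unlist(noise) < 0)) abort("noise levels must be >= 0.")
  check_positive(calibration_slope, "calibration_slope")
  structure(list(seed = as.integer(seed), protocol = protocol,
                 compliance = compliance, fluids = fluids,
                 aggregation = aggregation,
                 calibration_slope = calibration_slope, noise = noise),
            class = "synthetic_scenario")
}

#' Generate a noisy interface trace with ground truth
#'
#' Runs [simulate_linear()] under the scenario's protocol and adds Gaussian
#' noise with standard deviation `noise$beta_rel` times the on-segment
#' amplitude (`beta_ss - 1`). The noiseless trace and the true parameters
#' are attached as the `truth` attribute.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A `coflow_trace` tibble (`time_s`, `Q_T_mLh`, `Q_R_mLh`,
#'   `alpha`, `beta`) with attribute `truth` (list with `lambda_on`,
#'   `lambda_off`, `mu_T`, `beta_clean`).
#' @export
gen_beta_trace <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  clean <- simulate_linear(scenario$protocol, scenario$compliance,
                           scenario$fluids)
  amp <- steady_state_beta(scenario$protocol$Q_T_on, scenario$protocol$Q_R,
                           scenario$fluids$mu_T, scenario$fluids$mu_R) - 1
  sdev <- scenario$noise$beta_rel * amp
  noisy <- withr::with_seed(scenario$seed + 1L, {
    clean$beta + rnorm(nrow(clean), 0, sdev)
  })
  noisy <- pmax(noisy, 1)
  out <- clean
  out$beta <- noisy
  out$alpha <- 1 - 1 / noisy
  attr(out, "truth") <- list(lambda_on = scenario$compliance$lambda_on,
                             lambda_off = scenario$compliance$lambda_off,
                             mu_T = scenario$fluids$mu_T,
                             beta_clean = clean$beta)
  out
}

## Noise-free effective blood flow rate on the protocol grid: the set-point
## steps are low-pass filtered by the segment time constant.
q_effective <- function(scenario) {
  p <- scenario$protocol
  segs <- protocol_segments(p)
  grid <- seq(0, p$n_periods * p$period_s, by = p$dt)
  q <- numeric(length(grid))
  state <- 0
  for (i in seq_len(nrow(segs))) {
    lam <- if (segs$phase[i] == "on") scenario$compliance$lambda_on
           else scenario$compliance$lambda_off
    idx <- which(grid >= segs$t_start[i] - 1e-9 & grid <= segs$t_end[i] + 1e-9)
    rel <- grid[idx] - segs$t_start[i]
    q[idx] <- segs$Q_T[i] + (state - segs$Q_T[i]) * exp(-rel / lam)
    state <- q[idx[length(idx)]]
  }
  tmod <- grid %% p$period_s
  pump_on <- tmod < p$duty * p$period_s - 1e-9 &
    grid < p$n_periods * p$period_s - 1e-9
  tibble(time_s = grid, Q_eff_mLh = q, pump_on = pump_on)
}

#' Generate a blood velocity trace with ground truth
#'
#' The noise-free velocity is `U(t) = slope * Q_eff(t)` where the effective
#' flow rate relaxes toward each segment's set point with that segment's
#' time constant; Gaussian noise (`noise$velocity_mms`) is added.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A tibble `time_s`, `U_mms` with attribute `truth` (list with
#'   `U_clean`, `Q_eff_mLh`, `slope`).
#' @export
gen_velocity_trace <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  qe <- q_effective(scenario)
  u_clean <- scenario$calibration_slope * qe$Q_eff_mLh
  u <- withr::with_seed(scenario$seed + 2L, {
    u_clean + rnorm(length(u_clean), 0, scenario$noise$velocity_mms)
  })
  out <- tibble(time_s = qe$time_s, U_mms = u)
  attr(out, "truth") <- list(U_clean = u_clean, Q_eff_mLh = qe$Q_eff_mLh,
                             slope = scenario$calibration_slope)
  out
}

#' Generate a ROI-intensity trace with analytic aggregation truth
#'
#' Builds the intensity signal sample-by-sample as a first-order relaxation
#' toward a phase-dependent target: the pump-on baseline `I_base`
#' (dispersal, fast), a slightly dipped baseline `I_base - dip_gray` while
#' decaying flow persists above the gate velocity, and a saturating
#' aggregation rise of amplitude `A` (time scale `tau_agg_s`) once the
#' velocity falls below the gate. The analytic aggregation index over
#' `[t_gate, t_gate + ts]` is `A * (1 - (tau/ts) * (1 - exp(-ts/tau)))`
#' whenever the aggregation phase covers the span.
#'
#' @param scenario A [synthetic_scenario()].
#' @param ts Integration span used for the analytic truth (s). Default 60.
#' @return A tibble `time_s`, `I_mean` with attribute `truth` (list with
#'   `I_clean`, `t_gate` per period, `AI_analytic`).
#' @export
gen_intensity_trace <- function(scenario, ts = 60) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  agg <- scenario$aggregation
  qe <- q_effective(scenario)
  u <- scenario$calibration_slope * qe$Q_eff_mLh
  dt <- scenario$protocol$dt
  n <- nrow(qe)

  I <- numeric(n)
  I[1] <- agg$I_base
  phase <- character(n)
  gate_val <- NA_real_   # intensity at aggregation onset
  t_gate_now <- NA_real_
  t_gates <- numeric(0)
  for (k in 2:n) {
    aggregating <- !qe$pump_on[k] && u[k] < agg$u_gate_mms
    if (aggregating) {
      if (is.na(t_gate_now)) {
        t_gate_now <- qe$time_s[k]
        gate_val <- I[k - 1]
        t_gates <- c(t_gates, t_gate_now)
      }
      I[k] <- gate_val + agg$amplitude *
        (1 - exp(-(qe$time_s[k] - t_gate_now) / agg$tau_agg_s))
      phase[k] <- "agg"
    } else {
      if (!is.na(t_gate_now)) { t_gate_now <- NA_real_; gate_val <- NA_real_ }
      target <- if (qe$pump_on[k]) agg$I_base else agg$I_base - agg$dip_gray
      tau <- if (qe$pump_on[k]) agg$tau_disperse_s
             else scenario$compliance$lambda_off
      I[k] <- target + (I[k - 1] - target) * exp(-dt / tau)
      phase[k] <- if (qe$pump_on[k]) "on" else "decay"
    }
  }
  ai_analytic <- agg$amplitude *
    (1 - (agg$tau_agg_s / ts) * (1 - exp(-ts / agg$tau_agg_s)))
  noisy <- withr::with_seed(scenario$seed + 3L, {
    I + rnorm(n, 0, scenario$noise$intensity)
  })
  out <- tibble(time_s = qe$time_s, I_mean = noisy)
  attr(out, "truth") <- list(I_clean = I, t_gate = t_gates,
                             AI_analytic = ai_analytic, ts = ts)
  out
}

#' Generate a two-phase co-flow image stack with known interface
#'
#' Each frame is a two-level image: blood-gray columns up to
#' `round(alpha * width_px)` on the blood side, reference-gray beyond,
#' optionally softened by a 1-pixel edge blur, plus per-pixel Gaussian
#' noise.
#'
#' @param scenario A [synthetic_scenario()] (supplies the seed and the
#'   image noise level).
#' @param alpha Vector of true interface fractions, one per frame. `NULL`
#'   derives them from the noiseless circuit simulation.
#' @param width_px,height_px Frame size in pixels (width >= 100).
#' @param pixel_size Pixel scale (um/pixel).
#' @param gray_blood,gray_ref Gray levels of the two phases.
#' @param blur Edge blur in pixels (0 or 1).
#' @param noise_gray Per-pixel Gaussian noise sd; `NULL` uses the
#'   scenario's `noise$image_gray`.
#' @param blood_side `"left"` or `"right"`.
#' @return An [image_stack()] with attribute `truth` (the `alpha` vector).
#' @export
gen_coflow_stack <- function(scenario, alpha = NULL, width_px = 200,
                             height_px = 50, pixel_size = 5,
                             gray_blood = 40, gray_ref = 200, blur = 0,
                             noise_gray = NULL, blood_side = "left") {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (width_px < 100) abort("`width_px` must be >= 100.")
  if (is.null(alpha)) {
    alpha <- simulate_linear(scenario$protocol, scenario$compliance,
                             scenario$fluids)$alpha
  }
  if (any(alpha < 0 | alpha >= 1)) abort("true `alpha` must lie in [0, 1).")
  noise_gray <- noise_gray %||% scenario$noise$image_gray

  frames <- withr::with_seed(scenario$seed + 4L, {
    lapply(alpha, function(a) {
      cut <- round(a * width_px)
      row <- c(rep(gray_blood, cut), rep(gray_ref, width_px - cut))
      if (blood_side == "right") row <- rev(row)
      if (blur >= 1 && cut > 0 && cut < width_px) {
        row <- stats::filter(c(row[1], row, row[width_px]),
                             c(0.25, 0.5, 0.25), sides = 2)[2:(width_px + 1)]
      }
      f <- matrix(rep(row, each = height_px), nrow = height_px)
      if (noise_gray > 0) f <- f + matrix(rnorm(length(f), 0, noise_gray),
                                          nrow = height_px)
      f
    })
  })
  stack <- image_stack(frames, dt = scenario$protocol$dt,
                       pixel_size = pixel_size,
                       roi = c(1, 1, height_px, width_px))
  attr(stack, "truth") <- list(alpha = alpha)
  stack
}
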