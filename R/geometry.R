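#' Channel geometry of the co-flow device
#'
#' Dimensions of the shallow rectangular channels, in micrometres. The test
#' channel and the co-flowing channel share the nominal width `W`; `W_lane`
#' is the width entering the hydraulic-resistance formula for the test-fluid
#' lane (by default the full channel width).
#'
#' @param W Channel width (um). Default 1000.
#' @param h Channel depth (um). Default 100.
#' @param L_cc Co-flowing channel length (um). Default 10000 (1 cm); the
#'   length only matters when a compliance value is converted to a time
#'   constant.
#' @param W_lane Lane width used in the resistance formula (um); defaults to
#'   `W`. Must satisfy `W_lane <= W`.
#'
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(W = 1000, h = 100, L_cc = 10000, W_lane = W) {
  check_positive(W, "W"); check_positive(h, "h")
  check_positive(L_cc, "L_cc"); check_positive(W_lane, "W_lane")
  if (W_lane > W) abort("`W_lane` must not exceed the channel width `W`.")
  structure(list(W = W, h = h, L_cc = L_cc, W_lane = W_lane),
            class = "channel_geometry")
}

#' Reference/test fluid pair
#'
#' @param mu_R Reference-fluid viscosity (cP).
#' @param mu_T Test-fluid viscosity (cP).
#' @param label_R,label_T Fluid labels used in outputs.
#' @return An object of class `fluid_pair`.
#' @export
fluid_pair <- function(mu_R = 1, mu_T = 2.95,
                       label_R = "reference", label_T = "test") {
  check_positive(mu_R, "mu_R"); check_positive(mu_T, "mu_T")
  structure(list(mu_R = mu_R, mu_T = mu_T,
                 label_R = label_R, label_T = label_T),
            class = "fluid_pair")
}

#' Periodic on-off pump protocol
#'
#' The reference pump runs continuously at `Q_R`; the test pump is switched
#' on for `duty * period_s` seconds at the start of each period and off for
#' the remainder.
#'
#' @param period_s Period T (s). Default 240.
#' @param duty Fraction of the period with the test pump on, in (0, 1).
#'   Default 0.5.
#' @param Q_R Reference flow rate (mL/h), constant. Default 0.5.
#' @param Q_T_on Test flow rate while on (mL/h). Default 0.5.
#' @param n_periods Number of periods simulated/analyzed. Default 3.
#' @param dt Sampling interval (s). Default 0.5.
#' @return An object of class `pump_protocol`.
#' @export
pump_protocol <- function(period_s = 240, duty = 0.5, Q_R = 0.5,
                          Q_T_on = 0.5, n_periods = 3, dt = 0.5) {
  check_positive(period_s, "period_s")
  if (duty <= 0 || duty >= 1) abort("`duty` must lie strictly in (0, 1).")
  check_positive(Q_R, "Q_R")
  if (Q_T_on < 0) abort("`Q_T_on` must be >= 0.")
  if (n_periods < 1 || n_periods != round(n_periods)) {
    abort("`n_periods` must be a positive integer.")
  }
  check_positive(dt, "dt")
  structure(list(period_s = period_s, duty = duty, Q_R = Q_R,
                 Q_T_on = Q_T_on, n_periods = as.integer(n_periods), dt = dt),
            class = "pump_protocol")
}

#' Air-compliance parameterization of the transient response
#'
#' The trapped air cavity (plus tubing and device elasticity) acts as a
#' fluidic capacitor and sets the first-order relaxation time of the
#' interface after each pump transition. The primary parameterization is the
#' pair of time constants `(lambda_on, lambda_off)` fitted from data; a
#' compliance value `C_T` (uL/Pa) may be given instead, from which
#' `lambda = F1 * F2 * C_T * R_WT` is derived via [lambda_from_compliance()].
#'
#' @param lambda_on Time constant after pump turn-on (s).
#' @param lambda_off Time constant after pump turn-off (s).
#' @param C_T Optional compliance (uL/Pa).
#' @return An object of class `compliance_pack`.
#' @export
compliance_pack <- function(lambda_on = 3.2, lambda_off = 5.9, C_T = NULL) {
  check_positive(lambda_on, "lambda_on")
  check_positive(lambda_off, "lambda_off")
  if (!is.null(C_T)) check_positive(C_T, "C_T")
  structure(list(lambda_on = lambda_on, lambda_off = lambda_off, C_T = C_T),
            class = "compliance_pack")
}

#' Hydraulic resistance of the test-fluid lane
#'
#' Lumped resistance of a shallow rectangular lane,
#' `R_WT = 12 * mu_T * L_cc / (W_lane * h^3)`, evaluated in SI units.
#'
#' @param geom A [channel_geometry()] object.
#' @param mu_T Test-fluid viscosity (cP).
#' @return Resistance in Pa s / m^3.
#' @examples
#' lane_resistance(channel_geometry(W = 1000, h = 100, L_cc = 1000), mu_T = 1)
#' # 1.2e10 Pa s / m^3
#' @export
lane_resistance <- function(geom, mu_T) {
  stopifnot(inherits(geom, "channel_geometry"))
  check_positive(mu_T, "mu_T")
  12 * cp_to_pas(mu_T) * um_to_m(geom$L_cc) /
    (um_to_m(geom$W_lane) * um_to_m(geom$h)^3)
}

#' Time constant implied by a compliance value
#'
#' `lambda = F1 * F2 * C_T * R_WT`, approximately `C_T * R_WT` since
#' `F1 * F2` is close to 1.
#'
#' @param C_T Compliance (uL/Pa).
#' @param R_WT Lane resistance (Pa s / m^3), e.g. from [lane_resistance()].
#' @param constants A [model_constants()] object.
#' @return Time constant in seconds.
#' @export
lambda_from_compliance <- function(C_T, R_WT, constants = model_constants()) {
  check_positive(C_T, "C_T"); check_positive(R_WT, "R_WT")
  constants$F1 * constants$F2 * ul_per_pa_to_si(C_T) * R_WT
}
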