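#' Constants of the linearized co-flow circuit model
#'
#' The co-flowing two-stream system is modelled as a discrete fluidic
#' circuit in which the interface is a virtual wall. The mismatch between
#' that simplification and the full flow field is absorbed by a quartic
#' correction polynomial `C_f(alpha)` (fitted against CFD on
#' `0.1 < alpha < 0.9`), and the nonlinear governing equation is reduced to
#' a first-order linear ODE in `beta = 1/(1 - alpha)` via two dimensionless
#' linearization coefficients `F1` and `F2`.
#'
#' @param F1,F2 Dimensionless linearization coefficients (defaults 1.112 and
#'   1.129). Both must be positive.
#' @param cf_coeffs Numeric vector of the five polynomial coefficients of
#'   `C_f(alpha)`, highest power first (alpha^4 ... alpha^0).
#' @param cf_alpha_range Open interval of validity of the polynomial.
#'
#' @return An object of class `model_constants`.
#' @examples
#' k <- model_constants()
#' correction_factor(0.5, k)
#' @export
model_constants <- function(F1 = 1.112, F2 = 1.129,
                            cf_coeffs = c(6.6908, -13.382, 10.81, -4.1196, 1.6206),
                            cf_alpha_range = c(0.1, 0.9)) {
  check_positive(F1, "F1")
  check_positive(F2, "F2")
  if (length(cf_coeffs) != 5L || !is.numeric(cf_coeffs)) {
    abort("`cf_coeffs` must be five numeric polynomial coefficients (alpha^4 ... alpha^0).")
  }
  if (length(cf_alpha_range) != 2L || cf_alpha_range[1] >= cf_alpha_range[2]) {
    abort("`cf_alpha_range` must be an increasing interval.")
  }
  structure(
    list(F1 = F1, F2 = F2, cf_coeffs = as.numeric(cf_coeffs),
         cf_alpha_range = as.numeric(cf_alpha_range)),
    class = "model_constants"
  )
}

#' Correction factor of the virtual-wall circuit model
#'
#' Evaluates the quartic polynomial `C_f(alpha)` that compensates the
#' virtual-wall simplification of the co-flow circuit model. The polynomial
#' is only valid on an open interval of interface fractions
#' (default `0.1 < alpha < 0.9`).
#'
#' @param alpha Interface fraction(s), the blood-filled width divided by the
#'   channel width.
#' @param constants A [model_constants()] object.
#' @param mode `"strict"` (default) errors when `alpha` leaves the validity
#'   range; `"clamp"` clamps to the range with a warning.
#'
#' @return Numeric vector of correction-factor values.
#' @examples
#' correction_factor(0.5) # 1.008725
#' @export
correction_factor <- function(alpha, constants = model_constants(),
                              mode = c("strict", "clamp")) {
  mode <- match.arg(mode)
  rng <- constants$cf_alpha_range
  out_of_range <- alpha < rng[1] | alpha > rng[2]
  if (any(out_of_range)) {
    if (mode == "strict") {
      abort(sprintf(
        "alpha = %g outside the correction-factor validity range (%g, %g).",
        alpha[which(out_of_range)[1]], rng[1], rng[2]))
    }
    warn("alpha clamped to the correction-factor validity range.")
    alpha <- pmin(pmax(alpha, rng[1]), rng[2])
  }
  cf_eval(alpha, constants$cf_coeffs)
}

## bare polynomial evaluation, no range policing (internal hot path)
cf_eval <- function(alpha, coeffs) {
  ((((coeffs[1] * alpha + coeffs[2]) * alpha + coeffs[3]) * alpha +
      coeffs[4]) * alpha) + coeffs[5]
}

#' Convert between interface fraction and its linearizing transform
#'
#' `beta = 1/(1 - alpha)` linearizes the circuit model; `alpha = 1 - 1/beta`
#' inverts it. The round trip is exact in floating point for
#' `alpha` well inside `[0, 1)`.
#'
#' @param alpha Interface fraction in `[0, 1)`.
#' @param beta Linearized interface variable, `>= 1`.
#' @return Numeric vector.
#' @export
beta_from_alpha <- function(alpha) {
  if (any(alpha < 0 | alpha >= 1)) abort("`alpha` must lie in [0, 1).")
  1 / (1 - alpha)
}

#' @rdname beta_from_alpha
#' @export
alpha_from_beta <- function(beta) {
  if (any(beta < 1)) abort("`beta` must be >= 1.")
  1 - 1 / beta
}
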