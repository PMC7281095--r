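make_exp_trace <- function(lam, beta0 = 1, beta1 = 2.6, t_end = 60, dt = 0.5) {
  t <- seq(0, t_end, dt)
  tibble::tibble(time_s = t, beta = beta0 + beta1 * exp(-t / lam))
}

test_that("exponential fit recovers a noise-free time constant to 1e-6", {
  fit <- fit_time_constant(make_exp_trace(10))
  expect_equal(fit$lambda, 10, tolerance = 1e-6)
  expect_equal(fit$beta0, 1, tolerance = 1e-6)
  expect_equal(fit$beta1, 2.6, tolerance = 1e-6)
  expect_lt(fit$rms_residual, 1e-8)
  td <- tidy(fit)
  expect_equal(td$term, c("beta0", "beta1", "lambda"))
  expect_equal(glance(fit)$lambda, fit$lambda)
})

test_that("exponential fit is unbiased under small noise (Monte Carlo)", {
  t <- seq(0, 60, 0.5)
  clean <- 1 + 2.6 * exp(-t / 10)
  set.seed(123)
  errs <- replicate(100, {
    tr <- tibble::tibble(time_s = t, beta = clean + rnorm(length(t), 0, 0.005 * 2.6))
    abs(fit_time_constant(tr)$lambda - 10) / 10
  })
  expect_lt(mean(errs), 0.02)
})

test_that("degenerate transients are rejected", {
  flat <- tibble::tibble(time_s = seq(0, 60, 0.5), beta = 2)
  expect_error(fit_time_constant(flat), "degenerate")
  expect_error(fit_time_constant(make_exp_trace(10)[1:3, ]), "4 samples")
})

test_that("constant-flow viscosity inverts the steady state and flags beta = 1", {
  expect_equal(viscosity_constant_flow(3.61293, 1), 2.95, tolerance = 1e-5)
  expect_warning(mu <- viscosity_constant_flow(1, 1), "nonphysical")
  expect_equal(mu, 0)
  expect_error(viscosity_constant_flow(0.9, 1), "beta")
})

test_that("flow-corrected viscosity applies the Q_R/Q_B factor and the Q_min cut", {
  d <- tibble::tibble(time_s = c(0, 1, 2), beta = 2,
                      Q_B_mLh = c(1, 0.5, 0.05))
  out <- viscosity_varying_flow(d, mu_R = 1, Q_R = 1)
  expect_equal(nrow(out), 2L)  # Q_B = 0.05 excluded at the 0.1 mL/h floor
  expect_equal(out$mu_B_cP, c(1.129, 2.258), tolerance = 1e-9)
  expect_error(viscosity_varying_flow(d[3, ], mu_R = 1, Q_R = 1), "Q_min")
  # reduces to the constant-flow value when Q_B = Q_R
  d2 <- tibble::tibble(time_s = 0:5, beta = 3.61293, Q_B_mLh = 1)
  expect_equal(viscosity_varying_flow(d2, 1, 1)$mu_B_cP,
               rep(viscosity_constant_flow(3.61293, 1), 6))
})

test_that("flow-corrected viscosity recovers a constant viscosity from decaying flow", {
  # construct beta(t) consistent with mu_B = 3 cP while Q_B decays
  t <- seq(0, 30, 0.5)
  Q_B <- 1 * exp(-t / 10)
  k <- model_constants()
  beta <- 1 + 3 / (1 * k$F2) * Q_B / 1
  d <- tibble::tibble(time_s = t, beta = beta, Q_B_mLh = Q_B)
  out <- viscosity_varying_flow(d, mu_R = 1, Q_R = 1)
  expect_true(all(abs(out$mu_B_cP - 3) / 3 < 0.01))
  expect_true(all(out$Q_B_mLh >= 0.1))
})

test_that("shear rate follows 6Q/(W h^2) with unit conversion", {
  g <- channel_geometry(W = 1000, h = 100)
  expect_equal(shear_rate(0, g), 0)
  expect_equal(shear_rate(0.5, g), 83.3333, tolerance = 1e-5)
  expect_equal(shear_rate(1, g), 2 * shear_rate(0.5, g))
})

test_that("equivalent diameter matches area conservation", {
  expect_equal(round(equivalent_diameter(650, 100)), 288)
  expect_equal(round(equivalent_diameter(680, 100)), 294)
  s <- 123
  expect_equal(equivalent_diameter(s, s), 2 * s / sqrt(pi))
})

test_that("Maxwell elasticity reproduces the printed viscosity/time-constant pairs", {
  expect_equal(elasticity(2.95, 5.9), 0.5, tolerance = 1e-9)
  expect_equal(elasticity(5.89, 7.456), 0.79, tolerance = 0.001)
  expect_equal(elasticity(2.95, 59), elasticity(2.95, 5.9) / 10)
  expect_equal(elasticity(2 * 2.95, 5.9), 2 * elasticity(2.95, 5.9))
  expect_error(elasticity(1, 0), "lam")
})

test_that("t0 is the earliest minimum of the intensity window", {
  t <- seq(100, 160, 0.5)
  v <- abs(t - 130)  # V shape
  expect_equal(find_t0(tibble::tibble(time_s = t, I_mean = v)), 130)
  inc <- tibble::tibble(time_s = t, I_mean = t)
  expect_equal(find_t0(inc, window = c(120, 160)), 120)
  two <- tibble::tibble(time_s = t, I_mean = 5)
  two$I_mean[two$time_s %in% c(125, 140)] <- 1
  expect_equal(find_t0(two), 125)
  expect_error(find_t0(inc, window = c(500, 600)), "empty")
})

test_that("aggregation index integrates the rise above the minimum", {
  t <- seq(0, 100, 0.5)
  expect_equal(aggregation_index(tibble::tibble(time_s = t, I_mean = 7),
                                 t0 = 10, ts = 60)$AI, 0)
  # linear ramp of slope m from t0: AI = m * ts / 2 (trapezoid-exact)
  m <- 0.3
  ramp <- tibble::tibble(time_s = t, I_mean = pmax(0, t - 10) * m)
  expect_equal(aggregation_index(ramp, 10, 60)$AI, m * 60 / 2, tolerance = 1e-12)
  # saturating exponential rise: closed-form A*(1 - (tau/ts)(1 - exp(-ts/tau)))
  A <- 10; tau <- 20; ts <- 60
  sat <- tibble::tibble(time_s = t, I_mean = 50 + A * (1 - exp(-pmax(0, t - 10) / tau)))
  ai <- aggregation_index(sat, 10, ts)$AI
  expect_equal(ai, A * (1 - (tau / ts) * (1 - exp(-ts / tau))), tolerance = 0.02)
  expect_error(aggregation_index(sat, 80, 60), "exceeds")
})

test_that("aggregation index is shift-invariant and gain-linear", {
  t <- seq(0, 100, 0.5)
  set.seed(5)
  I <- 50 + cumsum(abs(rnorm(length(t), 0.1, 0.05)))
  base <- aggregation_index(tibble::tibble(time_s = t, I_mean = I), 5, 60)$AI
  shifted <- aggregation_index(tibble::tibble(time_s = t, I_mean = I + 33), 5, 60)$AI
  gained <- aggregation_index(tibble::tibble(time_s = t, I_mean = 3 * I), 5, 60)$AI
  expect_equal(shifted, base, tolerance = 1e-12)
  expect_equal(gained, 3 * base, tolerance = 1e-12)
})

test_that("velocity calibration converts velocities back to flow rates", {
  d <- tibble::tibble(time_s = 0:3, U_mms = c(2.0732, 0, 1.0366, 4.1464))
  out <- velocity_to_flow(d, velocity_calibration(2.0732))
  expect_equal(out$Q_B_mLh, c(1, 0, 0.5, 2))
  out2 <- velocity_to_flow(tibble::tibble(time_s = 0, U_mms = 1.31435),
                           velocity_calibration(2.6287))
  expect_equal(out2$Q_B_mLh, 0.5, tolerance = 1e-9)
  expect_error(velocity_calibration(-1), "slope")
})

test_that("velocity calibration fit recovers a through-origin slope", {
  Q <- seq(0.1, 1, 0.1)
  set.seed(21)
  d <- tibble::tibble(Q_mLh = Q, U_mms = 2.6287 * Q + rnorm(10, 0, 0.01))
  cal <- fit_velocity_calibration(d)
  expect_equal(cal$slope, 2.6287, tolerance = 0.01)
  expect_gt(cal$r_squared, 0.99)
  expect_equal(glance(cal)$slope, cal$slope)
})

test_that("power-law fit handles Newtonian, exact and noisy data", {
  g <- 10^seq(0, 2, length.out = 50)
  newt <- power_law_fit(tibble::tibble(gamma_dot = g, mu_cP = 3))
  expect_equal(newt$mu0, 3, tolerance = 1e-12)
  expect_equal(newt$n, 1, tolerance = 1e-12)

  exact <- power_law_fit(tibble::tibble(gamma_dot = g, mu_cP = 10 * g^(0.8 - 1)))
  expect_equal(exact$mu0, 10, tolerance = 1e-9)
  expect_equal(exact$n, 0.8, tolerance = 1e-9)

  set.seed(77)
  noisy <- power_law_fit(tibble::tibble(gamma_dot = g,
                                        mu_cP = 10 * g^(-0.2) * exp(rnorm(50, 0, 0.02))))
  expect_lt(abs(noisy$n - 0.8), 0.02)
  expect_error(power_law_fit(tibble::tibble(gamma_dot = c(-1, 1, 2), mu_cP = 1)),
               "positive")
  expect_error(power_law_fit(tibble::tibble(gamma_dot = 1:2, mu_cP = 1)), "3")
})

test_that("alpha/beta transforms round-trip exactly", {
  a <- seq(0, 0.99, 0.01)
  expect_equal(alpha_from_beta(beta_from_alpha(a)), a, tolerance = 1e-12)
  expect_error(beta_from_alpha(1), "alpha")
  expect_error(alpha_from_beta(0.5), "beta")
})
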