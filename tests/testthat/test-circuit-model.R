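test_that("correction factor reproduces direct polynomial evaluation and range policy", {
  expect_equal(correction_factor(0.5), 1.008725, tolerance = 1e-7)
  expect_equal(correction_factor(0.1), 1.30402708, tolerance = 1e-7)
  expect_error(correction_factor(0.95), "validity range")
  expect_warning(out <- correction_factor(0.95, mode = "clamp"), "clamped")
  expect_equal(out, correction_factor(0.9))
})

test_that("lane resistance follows the 12 mu L / (W h^3) scaling in SI units", {
  g <- channel_geometry(W = 1000, h = 100, L_cc = 1000)
  expect_equal(lane_resistance(g, 1), 1.2e10, tolerance = 1e-12)
  expect_equal(lane_resistance(channel_geometry(W = 1000, h = 100, L_cc = 2000), 1),
               2 * lane_resistance(g, 1))
  expect_equal(lane_resistance(channel_geometry(W = 1000, h = 50, L_cc = 1000), 1),
               8 * lane_resistance(g, 1))
  expect_error(channel_geometry(W = -1), "positive")
  expect_error(channel_geometry(W = 500, W_lane = 600), "exceed")
})

test_that("steady-state beta matches the closed form and its degenerate limits", {
  expect_equal(steady_state_beta(0, 1, 2.95, 1), 1)
  expect_equal(steady_state_alpha(0, 1, 2.95, 1), 0)
  expect_equal(steady_state_beta(1, 1, 1, 1), 1 + 1 / 1.129, tolerance = 1e-9)
  expect_equal(steady_state_beta(1, 1, 2.95, 1), 3.61293, tolerance = 1e-5)
  expect_equal(steady_state_alpha(1, 1, 2.95, 1), 0.72321, tolerance = 1e-5)
  expect_error(steady_state_beta(1, 0, 1, 1), "Q_R")
})

test_that("time constant from compliance is linear in C_T and R_WT", {
  g <- channel_geometry()
  r <- lane_resistance(g, 2)
  expect_equal(lambda_from_compliance(2, r), 2 * lambda_from_compliance(1, r))
  expect_equal(lambda_from_compliance(1, 2 * r), 2 * lambda_from_compliance(1, r))
  k <- model_constants()
  expect_equal(lambda_from_compliance(1, r), k$F1 * k$F2 * 1e-9 * r)
})

test_that("linear simulation matches the per-segment analytic exponential", {
  p <- pump_protocol(period_s = 240, duty = 0.5, n_periods = 2)
  cp <- compliance_pack(lambda_on = 10, lambda_off = 20)
  fl <- fluid_pair(mu_R = 1, mu_T = 2.95)
  tr <- simulate_linear(p, cp, fl)
  bss_on <- steady_state_beta(p$Q_T_on, p$Q_R, fl$mu_T, fl$mu_R)

  # first on segment from beta = 1
  on1 <- tr$time_s <= 120
  exact_on <- bss_on + (1 - bss_on) * exp(-tr$time_s[on1] / 10)
  expect_lt(max(abs(tr$beta[on1] - exact_on) / exact_on), 1e-6)

  # first off segment decays from the on-segment end toward 1
  off1 <- tr$time_s >= 120 & tr$time_s <= 240
  b120 <- tr$beta[tr$time_s == 120]
  exact_off <- 1 + (b120 - 1) * exp(-(tr$time_s[off1] - 120) / 20)
  expect_lt(max(abs(tr$beta[off1] - exact_off) / exact_off), 1e-6)

  # residual of the off step amplitude at the end of the off segment
  expect_lt(abs(tr$beta[tr$time_s == 240] - 1), 0.01 * (b120 - 1) + 1e-9)

  # trace-level invariants
  expect_true(all(tr$beta >= 1))
  expect_true(all(tr$alpha >= 0 & tr$alpha < 1))
  expect_equal(tr$beta, 1 / (1 - tr$alpha))
})

test_that("each constant-flow segment is monotone toward its steady state", {
  tr <- simulate_linear(pump_protocol(n_periods = 2), compliance_pack(5, 15),
                        fluid_pair(mu_R = 1, mu_T = 3))
  segs <- split(tr, cumsum(c(TRUE, diff(tr$Q_T_mLh) != 0)))
  for (s in segs) {
    if (nrow(s) < 3) next
    d <- diff(s$beta)
    expect_true(all(d >= -1e-9) || all(d <= 1e-9))
  }
})

test_that("a very small time constant reaches steady state within one sample", {
  p <- pump_protocol(period_s = 20, duty = 0.5, n_periods = 1, dt = 0.5)
  tr <- simulate_linear(p, compliance_pack(0.01, 0.01), fluid_pair(1, 2))
  bss <- steady_state_beta(p$Q_T_on, p$Q_R, 2, 1)
  expect_equal(tr$beta[tr$time_s == 0.5], bss, tolerance = 1e-8)
})

test_that("beta_init below 1 is rejected", {
  expect_error(simulate_linear(pump_protocol(), compliance_pack(), fluid_pair(),
                               beta_init = 0.9), "beta_init")
})

test_that("nonlinear steady states agree with the linearization within 6%", {
  a_nl <- steady_state_alpha_nonlinear(1, 1, 1, 1)
  a_lin <- steady_state_alpha(1, 1, 1, 1)
  expect_lt(abs(a_nl - a_lin) / a_nl, 0.06)
  # long-run simulation converges to the algebraic root
  tr <- simulate_nonlinear(pump_protocol(period_s = 400, duty = 0.95, n_periods = 1),
                           fluids = fluid_pair(mu_R = 1, mu_T = 1),
                           tau_s = 40, alpha_init = 0.3)
  expect_equal(tr$alpha[tr$time_s == 380], a_nl, tolerance = 1e-4)
})

test_that("nonlinear and linear traces agree within 10% inside the interface band", {
  p <- pump_protocol(period_s = 80, duty = 0.75, n_periods = 1)
  tau <- 40
  k <- model_constants()
  lam <- k$F1 * k$F2 * tau
  fl <- fluid_pair(mu_R = 1, mu_T = 1)
  nl <- simulate_nonlinear(p, fluids = fl, tau_s = tau, alpha_init = 0.25)
  li <- simulate_linear(p, compliance_pack(lambda_on = lam, lambda_off = lam),
                        fl, beta_init = 1 / (1 - 0.25))
  band <- nl$alpha >= 0.15 & nl$alpha <= 0.85
  expect_true(any(band))
  expect_lt(max(abs(nl$beta[band] - li$beta[band]) / li$beta[band]), 0.10)
})

test_that("nonlinear model decays monotonically with the test pump held off", {
  tr <- simulate_nonlinear(pump_protocol(period_s = 20, duty = 0.5, Q_T_on = 0,
                                         n_periods = 1),
                           fluids = fluid_pair(mu_R = 1, mu_T = 1),
                           tau_s = 40, alpha_init = 0.6)
  expect_true(all(diff(tr$alpha) < 0))
})

test_that("nonlinear integration reports a domain error naming the failure time", {
  err <- tryCatch(
    simulate_nonlinear(pump_protocol(period_s = 200, duty = 0.5, n_periods = 1),
                       fluids = fluid_pair(mu_R = 1, mu_T = 1),
                       tau_s = 5, alpha_init = 0.25),
    error = function(e) conditionMessage(e))
  expect_match(err, "at t = ")
  expect_error(
    simulate_nonlinear(pump_protocol(), fluids = fluid_pair(), tau_s = 5,
                       alpha_init = 0.12),
    "invertible branch")
})

test_that("steady-state viscosity inversion round-trips exactly", {
  for (mu in c(1, 3, 6)) {
    b <- steady_state_beta(1, 1, mu, 1)
    expect_equal(viscosity_constant_flow(b, 1), mu, tolerance = 1e-12)
  }
})
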