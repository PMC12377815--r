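test_that("SEE force is a quadratic spring anchored at the strain parameter", {
  pars <- test_pars()
  el <- pars$elastic
  # slack case
  expect_identical(see_force(el$see_slack, pars), 0)
  expect_identical(see_force(0.5 * el$see_slack, pars), 0)
  # force equals f_max exactly at the defining strain (4%)
  expect_equal(see_force(el$see_slack * (1 + el$see_strain_at_fmax), pars),
               el$f_max_ce)
  # quadratic scaling: half the strain gives a quarter of the force
  expect_equal(see_force(el$see_slack * (1 + el$see_strain_at_fmax / 2), pars),
               el$f_max_ce / 4)
  expect_error(see_force(NaN, pars), "finite")
  expect_error(see_force(-1e-3, pars), ">= 0")
})

test_that("PEE force is slack below 0.9 l_opt and quadratic above", {
  pars <- test_pars()
  el <- pars$elastic
  slack <- el$pee_slack_rel * el$l_ce_opt
  expect_identical(pee_force(slack, pars), 0)
  # doubling the extension quadruples the force
  f1 <- pee_force(slack + 0.2e-3, pars)
  f2 <- pee_force(slack + 0.4e-3, pars)
  expect_equal(f2, 4 * f1)
  # passive force at optimum is of order 1% of maximum force
  expect_lt(pee_force(el$l_ce_opt, pars) / el$f_max_ce, 0.05)
  expect_gt(pee_force(el$l_ce_opt, pars) / el$f_max_ce, 1e-3)
})

test_that("elastic forces are C1 at slack", {
  pars <- test_pars()
  el <- pars$elastic
  # tangent stiffness is continuous through slack: zero on both sides,
  # negligible just above, relative to the operating-point stiffness
  k_op <- huxmtc:::see_stiffness(el$see_slack * (1 + el$see_strain_at_fmax),
                                 pars)
  eps <- 1e-9
  expect_identical(huxmtc:::see_stiffness(el$see_slack, pars), 0)
  expect_lt(huxmtc:::see_stiffness(el$see_slack + eps, pars) / k_op, 1e-4)
  pee_slack <- el$pee_slack_rel * el$l_ce_opt
  k_op_p <- huxmtc:::pee_stiffness(el$l_ce_opt, pars)
  expect_identical(huxmtc:::pee_stiffness(pee_slack, pars), 0)
  expect_lt(huxmtc:::pee_stiffness(pee_slack + eps, pars) / k_op_p, 1e-4)
})

test_that("isometric force-length is a clamped quartic, even about optimum", {
  expect_identical(isometric_force_length(1), 1)
  # even in (l - 1)
  d <- c(0.05, 0.1, 0.2, 0.3)
  expect_equal(isometric_force_length(1 + d), isometric_force_length(1 - d))
  # a genuine 4th-order polynomial inside the support: 5 points determine it
  xs <- seq(0.9, 1.1, length.out = 5)
  co <- coef(lm(isometric_force_length(xs) ~ poly(xs, 4, raw = TRUE)))
  probe <- seq(0.88, 1.12, by = 0.01)
  poly_val <- cbind(1, outer(probe, 1:4, `^`)) %*% co
  expect_equal(as.numeric(poly_val), isometric_force_length(probe),
               tolerance = 1e-10)
  # clamped to [0, 1] outside the fitted range
  expect_identical(isometric_force_length(c(0.2, 2.5)), c(0, 0))
  expect_true(all(isometric_force_length(seq(0.3, 2, by = 0.01)) <= 1))
  # support endpoints at 1 +/- sqrt(-2/shape)
  r <- sqrt(-2 / -16)
  expect_equal(isometric_force_length(1 + r - 1e-9), 0, tolerance = 1e-6)
  expect_identical(isometric_force_length(1 + r + 1e-9), 0)
})

test_that("active state is a floored Hill sigmoid with q(kappa) = 0.5", {
  pars <- test_pars()
  a <- pars$activation
  expect_equal(active_state(a$kappa, pars), 0.5)
  expect_identical(active_state(0, pars), a$q_min)
  # saturation value at gamma = 1
  expect_equal(active_state(1, pars), 1 / (1 + a$kappa^a$n_coop))
  # monotone non-decreasing
  g <- seq(0, 1, by = 0.01)
  expect_true(all(diff(active_state(g, pars)) >= 0))
  expect_true(all(active_state(g, pars) >= a$q_min))
  expect_error(active_state(1.2, pars), "0, 1")
})

test_that("calcium dynamics follow first-order closed forms", {
  pars <- test_pars()
  a <- pars$activation
  # fixed point at stim level
  expect_equal(calcium_rate(1, 1, pars), 0)
  expect_equal(calcium_rate(0, 0, pars), 0)
  # analytic decay: gamma(t) = g0 exp(-t / tau_deact)
  g0 <- 0.8
  dt <- 1e-5
  g <- g0
  for (i in seq_len(2000)) {   # RK4, 20 ms
    k1 <- calcium_rate(g, 0, pars)
    k2 <- calcium_rate(g + dt / 2 * k1, 0, pars)
    k3 <- calcium_rate(g + dt / 2 * k2, 0, pars)
    k4 <- calcium_rate(g + dt * k3, 0, pars)
    g <- g + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_equal(g, g0 * exp(-0.02 / a$tau_deact), tolerance = 1e-9)
  # rise time scales with tau_act: time to reach 1 - 1/e of the step
  for (tau in c(0.02, 0.05, 0.09)) {
    ai <- activation_parameters(tau_act = tau)
    g <- 0; t <- 0; dt <- 1e-5
    while (g < 1 - exp(-1)) {
      g <- g + dt * calcium_rate(g, 1, ai)
      t <- t + dt
    }
    expect_equal(t, tau, tolerance = 0.01)
  }
})

test_that("sliding velocity scales by 2 n_sarc h with shortening positive", {
  pars <- test_pars()
  expect_identical(sliding_velocity(0, pars), 0)
  # n_sarc = 6 mm / 2.4 um = 2500
  n_sarc <- pars$elastic$l_ce_opt / pars$scale$s_opt
  expect_equal(n_sarc, 2500)
  # shortening (negative CE velocity) gives positive u
  u <- sliding_velocity(-1e-3, pars)
  expect_equal(u, 1e-3 / (2 * 2500 * 1e-8))
  expect_gt(u, 0)
  # round trip: integrating u over a ramp recovers the CE length change
  dt <- 1e-4
  v <- function(tt) -2e-3 * sin(2 * pi * tt)      # m/s
  tt <- seq(0, 0.5, by = dt)
  du <- sliding_velocity(v(tt), pars)
  dl_from_u <- -trapz(tt, du) * 2 * n_sarc * pars$scale$h
  expect_equal(dl_from_u, trapz(tt, v(tt)), tolerance = 1e-12)
})
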