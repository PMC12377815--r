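test_that("distribution container enforces its invariants", {
  pars <- test_pars()
  x <- xb_grid(pars)
  expect_error(xb_distribution(rev(x), rep(0, length(x))), "increasing")
  expect_error(xb_distribution(x, rep(2, length(x))), "0, 1")
  d <- xb_steady_state(pars, drive = 0.7)
  expect_true(all(d$n >= 0 & d$n <= 0.7 + 1e-12))
  # boundary mass is negligible on the default grid
  expect_lt(max(d$n[1], d$n[length(d$n)]), 1e-10)
})

test_that("distribution_rate vanishes at the analytic fixed point and decays without drive", {
  pars <- test_pars()
  d <- xb_steady_state(pars, drive = 0.6)
  r <- distribution_rate(d, u = 0, drive = 0.6, pars)
  expect_lt(max(abs(r$dn)), 1e-9 * pars$rates$g2)
  expect_identical(r$dx, 0)
  # drive = 0: strictly non-positive rate wherever n > 0
  r0 <- distribution_rate(d, u = 0.5, drive = 0, pars)
  expect_true(all(r0$dn[d$n > 0] <= 0))
  expect_identical(r0$dx, -0.5)
})

test_that("relaxation from empty converges to the fixed point (oracle RK4)", {
  pars <- test_pars()
  x <- xb_grid(pars)
  drive <- 0.8
  # 50 / g1 seconds at a step stable for the stiff g2 branch
  n <- oracle_relax_u0(x, numeric(length(x)), function(tt) drive, pars,
                       t_end = 50 / pars$rates$g1, dt = 1e-4)
  target <- xb_steady_state(pars, drive = drive)$n
  expect_lt(max(abs(n - target)), 1e-6)
})

test_that("ce_force is the normalized first moment, linear in n", {
  pars <- test_pars()
  x <- xb_grid(pars)
  zero <- xb_distribution(x, numeric(length(x)))
  expect_identical(ce_force(zero, pars), 0)
  # isometric steady state at full drive gives exactly f_max
  d1 <- xb_steady_state(pars, drive = 1)
  expect_equal(ce_force(d1, pars), pars$elastic$f_max_ce)
  # linearity
  d_half <- xb_distribution(x, 0.5 * d1$n)
  expect_equal(ce_force(d_half, pars), 0.5 * pars$elastic$f_max_ce)
  expect_error(ce_force(d1, pars, m1_iso = 0), "> 0")
})

test_that("lce_rate is zero in static equilibrium and finite in degenerate slack", {
  pars <- test_pars()
  el <- pars$elastic
  l_mtc <- test_opt_length(pars)
  st <- initialize_state(l_mtc, pars)
  # the resting state is a gamma fixed point only at stim = 0; drive at
  # q_min gives a fully consistent static equilibrium
  rate <- lce_rate(st, l_mtc, 0, pars)
  expect_lt(abs(rate), 1e-10)
  # slack everything: rate must be finite (regularized), not NaN
  st2 <- st
  st2$l_ce <- 0.8 * el$l_ce_opt
  r2 <- lce_rate(st2, st2$l_ce + 0.5 * el$see_slack, 0, pars)
  expect_true(is.finite(r2))
})

test_that("steady-state force-velocity has Huxley-type shape", {
  pars <- test_pars()
  # physiological filament velocities: u ~ v_ce / (2 n_sarc h), so a few
  # hundred per second spans rest to near-maximal shortening
  u <- c(-500, -400, -300, -200, -100, -50, 0, 50, 100, 200, 400, 800, 1600)
  fv <- force_velocity(u, pars, drive = 1)
  f0 <- fv$f_rel[fv$u == 0]
  expect_equal(f0, 1, tolerance = 1e-3)
  # monotone decreasing with shortening velocity
  short <- fv[fv$u >= 0, ]
  expect_true(all(diff(short$f_rel) <= 0))
  # lengthening exceeds isometric force
  expect_true(all(fv$f_rel[fv$u < 0] > f0))
  # with g3 > 0 the eccentric limb plateaus: the force gain per unit of
  # lengthening speed shrinks as lengthening gets faster
  gain_slow <- fv$f_rel[fv$u == -100] - fv$f_rel[fv$u == -50]
  gain_fast <- fv$f_rel[fv$u == -500] - fv$f_rel[fv$u == -400]
  expect_lt(gain_fast, gain_slow)
  expect_lt(max(fv$f_rel), 2)
})
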