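test_that("initialization is consistent, deterministic, and handles slack", {
  pars <- test_pars()
  el <- pars$elastic
  l0 <- test_opt_length(pars)
  st <- initialize_state(l0, pars)
  resid <- see_force(l0 - st$l_ce, pars) -
    ce_force(st$distribution, pars) - pee_force(st$l_ce, pars)
  # the distribution fixed point at drive = q_min * F_isom carries force
  # f_max * drive, matching the root-solve target
  expect_lt(abs(resid), 1e-10 * el$f_max_ce)
  # determinism
  st2 <- initialize_state(l0, pars)
  expect_identical(st, st2)
  # slack MTC: no error; the SEE carries only the q_min floor force
  st3 <- initialize_state(0.9 * (el$see_slack + 0.9 * el$l_ce_opt), pars)
  expect_lt(see_force(0.9 * (el$see_slack + 0.9 * el$l_ce_opt) - st3$l_ce,
                      pars), 2 * pars$activation$q_min * el$f_max_ce)
  expect_error(initialize_state(-1, pars), "positive")
})

test_that("an unstimulated muscle holds its state for a second", {
  pars <- test_pars()
  l0 <- test_opt_length(pars)
  t <- seq(0, 1, by = 5e-4)
  inp <- simulation_input(t, rep(l0, length(t)), numeric(length(t)))
  sim <- simulate_mtc(inp, pars)
  expect_lt(max(abs(sim$f_see - sim$f_see[1])), 1e-3 * pars$elastic$f_max_ce)
  expect_lt(max(abs(sim$l_ce - sim$l_ce[1])), 1e-6 * pars$elastic$l_ce_opt)
})

test_that("a sustained tetanus approaches the saturated plateau below f_max", {
  pars <- test_pars()
  l0 <- test_opt_length(pars)
  p <- movement_protocol(kind = "isometric", offset_length = l0,
                         n_pulses = 90, pulse_rate = 150, lead_in = 0.05,
                         tail = 0.1)
  inp <- make_length_trajectory(p)
  sim <- simulate_mtc(inp, pars)
  f_pk <- max(sim$f_ce)
  expect_lt(f_pk, pars$elastic$f_max_ce)
  # plateau should reach the saturation drive level approximately
  q_sat <- 1 / (1 + pars$activation$kappa^pars$activation$n_coop)
  expect_gt(f_pk, 0.85 * q_sat * pars$elastic$f_max_ce)
  # force-balance residual bounded throughout
  expect_lt(attr(sim, "diagnostics")$max_residual, 1e-4)
})

test_that("simulation is reproducible bit-for-bit and converges with tolerance", {
  pars <- test_pars()
  l0 <- test_opt_length(pars)
  p <- movement_protocol(kind = "sinusoid", amplitude = 0.25e-3,
                         frequency = 2, offset_length = l0,
                         stim_phase = "concentric", n_cycles = 1,
                         lead_in = 0.05, tail = 0.1)
  inp <- make_length_trajectory(p)
  s1 <- simulate_mtc(inp, pars)
  s2 <- simulate_mtc(inp, pars)
  expect_identical(s1$f_see, s2$f_see)
  # halving the tolerance changes the force trace by < 0.1% RMS
  s3 <- simulate_mtc(inp, pars, sim_options(rtol = 5e-7, atol = 5e-10))
  rel_rms <- sqrt(mean((s3$f_see - s1$f_see)^2)) / max(s1$f_see)
  expect_lt(rel_rms, 1e-3)
})

test_that("quasi-state solution matches a root-solving oracle on a sinusoid", {
  pars <- test_pars()
  l0 <- test_opt_length(pars)
  p <- movement_protocol(kind = "sinusoid", amplitude = 0.25e-3,
                         frequency = 2, offset_length = l0,
                         stim_phase = "concentric", n_cycles = 1,
                         lead_in = 0.05, tail = 0.0)
  inp <- make_length_trajectory(p)
  t_end <- 0.5
  oracle <- oracle_rootsolve_mtc(pars, inp, t_end = t_end, dt = 1e-4)
  sim <- simulate_mtc(inp, pars)
  f_sim <- approx(sim$t, sim$f_see, xout = oracle$t)$y
  err <- sqrt(mean((f_sim - oracle$f_see)^2)) / max(oracle$f_see)
  expect_lt(err, 5e-3)
})

test_that("periodic steady-state energy bookkeeping closes", {
  pars <- test_pars()
  l0 <- test_opt_length(pars)
  # three cycles; analyse the third, where the loop is periodic
  p <- movement_protocol(kind = "sinusoid", amplitude = 0.25e-3,
                         frequency = 2, offset_length = l0,
                         stim_phase = "concentric", n_cycles = 3,
                         lead_in = 0.1, tail = 0.1)
  inp3 <- make_length_trajectory(p)
  # restimulate every cycle: build a 3-train stimulus by hand
  per <- 0.5
  on1 <- inp3$pulse_times
  pulse_times <- c(on1, on1 + per, on1 + 2 * per)
  stim <- huxmtc:::stim_signal(inp3$t, pulse_times, 0.004)
  inp3 <- simulation_input(inp3$t, inp3$l_mtc, stim,
                           pulse_times = pulse_times)
  sim <- simulate_mtc(inp3, pars)
  # stimulus-aligned windows fully inside the movement span
  w0 <- on1[1]
  cyc1 <- summary(sim, window = c(w0, w0 + per))
  cyc2 <- summary(sim, window = c(w0 + per, w0 + 2 * per))
  # periodicity: successive cycles perform nearly equal work
  expect_equal(cyc2$work_mtc, cyc1$work_mtc, tolerance = 0.02)
  # elastic storage cancels over a closed cycle: MTC work ~ CE work
  expect_lt(abs(cyc2$work_mtc - cyc2$work_ce), 0.01 * abs(cyc2$work_mtc))
})

test_that("work-loop efficiency is positive concentric, negative eccentric", {
  pars <- test_pars()
  l0 <- test_opt_length(pars)
  run <- function(phase) {
    p <- movement_protocol(kind = "sinusoid", amplitude = 0.25e-3,
                           frequency = 2, offset_length = l0,
                           stim_phase = phase, n_cycles = 2,
                           lead_in = 0.1, tail = 0.2)
    inp <- make_length_trajectory(p)
    sim <- simulate_mtc(inp, pars)
    per <- 0.5
    centre <- 0.1 + if (phase == "concentric") per / 2 else per
    summary(sim, window = c(centre - per / 2, centre + per / 2))
  }
  con <- run("concentric")
  ecc <- run("eccentric")
  expect_gt(con$work_mtc, 0)
  expect_lt(ecc$work_mtc, 0)
  expect_gt(con$efficiency, 0.01)
  expect_lt(con$efficiency, 1)
  expect_lt(ecc$efficiency, 0)
})

test_that("doubling grid resolution barely changes forces and powers", {
  pars <- test_pars()
  l0 <- test_opt_length(pars)
  p <- movement_protocol(kind = "sinusoid", amplitude = 0.25e-3,
                         frequency = 2, offset_length = l0,
                         stim_phase = "concentric", n_cycles = 1,
                         lead_in = 0.05, tail = 0.15)
  inp <- make_length_trajectory(p)
  s1 <- simulate_mtc(inp, pars)
  pars2 <- pars
  pars2$grid <- grid_parameters(n_nodes = 401L)
  s2 <- simulate_mtc(inp, pars2)
  expect_lt(sqrt(mean((s2$f_see - s1$f_see)^2)) / max(s1$f_see), 5e-3)
  m1 <- mean(s1$p_total); m2 <- mean(s2$p_total)
  expect_lt(abs(m2 - m1) / m1, 5e-3)
})

test_that("results round-trip to CSV with a summary JSON", {
  pars <- test_pars()
  l0 <- test_opt_length(pars)
  t <- seq(0, 0.2, by = 5e-4)
  inp <- simulation_input(t, rep(l0, length(t)),
                          huxmtc:::stim_signal(t, 0.05, 0.004),
                          pulse_times = 0.05)
  sim <- simulate_mtc(inp, pars)
  path <- withr::local_tempfile(fileext = ".csv")
  write_result_csv(sim, path)
  back <- read.csv(path)
  expect_equal(back$f_see, sim$f_see, tolerance = 1e-12)
  expect_true(file.exists(sub("\\.csv$", "_summary.json", path)))
})
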