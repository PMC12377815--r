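test_that("stimulus trains are block pulses at the requested rate", {
  s <- make_stimulus(n_pulses = 5, rate = 100, onset = 0.1)
  on <- attr(s, "pulse_times")
  expect_length(on, 5)
  expect_equal(diff(on), rep(0.01, 4))
  expect_equal(attr(s, "pulse_width"), 0.004)
  # exactly 5 rising edges in the sampled signal
  expect_equal(sum(diff(s$stim) > 0.5), 5)
  # block area: integral = n * width (sampled at 2 kHz, width = 8 samples)
  expect_equal(sum(s$stim) / 2000, 5 * 0.004, tolerance = 1e-9)
  # single pulse
  s1 <- make_stimulus(1)
  expect_equal(sum(diff(s1$stim) > 0.5), 1)
  expect_error(make_stimulus(3, rate = 300, width = 0.004), "overlap")
})

test_that("length trajectories are periodic sinusoids or constant holds", {
  pars <- test_pars()
  l0 <- test_opt_length(pars)
  iso <- make_length_trajectory(
    movement_protocol(kind = "isometric", offset_length = l0))
  expect_true(all(iso$l_mtc == l0))
  p <- movement_protocol(kind = "sinusoid", amplitude = 0.25e-3,
                         frequency = 2, offset_length = l0,
                         stim_phase = "concentric", n_cycles = 2)
  sin_in <- make_length_trajectory(p)
  expect_equal(max(sin_in$l_mtc), l0 + 0.25e-3, tolerance = 1e-9)
  expect_equal(min(sin_in$l_mtc), l0 - 0.25e-3, tolerance = 1e-9)
  # exactly periodic over cycles during the movement
  t <- sin_in$t
  moving <- t >= 0.1 & t <= 0.1 + 0.5
  shifted <- t >= 0.6 & t <= 1.1
  expect_equal(sin_in$l_mtc[moving], sin_in$l_mtc[shifted], tolerance = 1e-12)
  # 0.25 mm on a ~6 mm fibre: relative excursion ~ 4%
  expect_equal(0.25e-3 / pars$elastic$l_ce_opt, 0.042, tolerance = 0.01)
  expect_error(make_length_trajectory(p, sample_rate = 30), "20x")
})

test_that("concentric and eccentric stimulus onsets differ by half a period", {
  pars <- test_pars()
  l0 <- test_opt_length(pars)
  mk <- function(phase) {
    make_length_trajectory(movement_protocol(
      kind = "sinusoid", amplitude = 0.25e-3, frequency = 2,
      offset_length = l0, stim_phase = phase, n_cycles = 2))
  }
  con <- mk("concentric")
  ecc <- mk("eccentric")
  per <- 0.5
  expect_equal(ecc$pulse_times[1] - con$pulse_times[1], per / 2,
               tolerance = 1e-9)
  # the concentric train spans shortening: dl/dt < 0 at every onset
  lm_fun <- splinefun(con$t, con$l_mtc)
  expect_true(all(lm_fun(con$pulse_times, deriv = 1) < 0))
  expect_true(all(lm_fun(ecc$pulse_times, deriv = 1) > 0))
})

test_that("inputs round-trip through CSV in both unit conventions", {
  pars <- test_pars()
  inp <- make_length_trajectory(movement_protocol(
    kind = "sinusoid", amplitude = 0.25e-3, frequency = 2,
    offset_length = test_opt_length(pars)))
  for (unit in c("m", "mm")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_input_csv(inp, path, unit = unit)
    back <- read_input_csv(path, unit = unit)
    expect_equal(back$l_mtc, inp$l_mtc, tolerance = 1e-12)
    expect_equal(back$stim, inp$stim)
    # pulse times reconstructed from edges
    expect_equal(back$pulse_times, inp$pulse_times, tolerance = 1e-9)
  }
})
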