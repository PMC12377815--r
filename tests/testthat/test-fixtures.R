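test_that("bundle sampling is deterministic and respects the declared ranges", {
  b1 <- sample_bundle(seed = 99)
  b2 <- sample_bundle(seed = 99)
  expect_identical(b1, b2)
  rng <- bundle_ranges()
  draws <- lapply(1:200, function(i) sample_bundle(seed = i))
  get <- function(fn) vapply(draws, fn, numeric(1))
  f_max <- get(function(b) b$pars$elastic$f_max_ce)
  expect_true(all(f_max >= rng$f_max_ce[1] & f_max <= rng$f_max_ce[2]))
  tau_a <- get(function(b) b$pars$activation$tau_act)
  expect_true(all(tau_a >= rng$tau_act[1] & tau_a <= rng$tau_act[2]))
  c3 <- get(function(b) b$pars$energetic$c3)
  expect_true(all(c3 >= rng$c3[1] & c3 <= rng$c3[2]))
  g2 <- get(function(b) b$pars$rates$g2)
  expect_true(all(g2 >= rng$g2[1] & g2 <= rng$g2[2]))
  # geometric consistency: slack lengths below operating lengths
  ok <- vapply(draws, function(b) {
    el <- b$pars$elastic
    el$see_slack < el$l_ce_opt && el$pee_slack_rel * el$l_ce_opt < el$l_ce_opt
  }, logical(1))
  expect_true(all(ok))
  # both readings of the PEE shape column are available
  rng_raw <- bundle_ranges("table_raw")
  expect_equal(rng_raw$pee_shape, c(0.16, 1.0))
})

test_that("noiseless trials equal their generating simulations exactly", {
  b <- sample_bundle(seed = 21)
  trs <- generate_trials(b, default_protocols(reduced = TRUE), noise = FALSE,
                         components = c("force_frequency", "dynamic"))
  for (tr in trs) {
    sim <- simulate_mtc(tr$input, b$pars)
    expect_identical(tr$measured_force, sim$f_see)
  }
})

test_that("trial generation is reproducible and labels are coherent", {
  b <- sample_bundle(seed = 22)
  trs1 <- generate_trials(b, default_protocols(reduced = TRUE))
  trs2 <- generate_trials(b, default_protocols(reduced = TRUE))
  expect_identical(trs1, trs2)
  kinds <- vapply(trs1, function(tr) tr$trial_kind, character(1))
  expect_setequal(unique(kinds), c("static_fl", "force_frequency",
                                   "dynamic", "metabolic"))
  met <- Filter(function(tr) tr$trial_kind == "metabolic", trs1)
  expect_true(all(vapply(met, function(tr)
    !is.null(tr$measured_mean_power), logical(1))))
  # repeated-measure condition duplicated with independent noise
  reps <- Filter(function(tr) grepl("met_0.25mm_2Hz_con_r", tr$id), met)
  expect_equal(length(reps), 2L)
  expect_false(reps[[1]]$measured_mean_power == reps[[2]]$measured_mean_power)
})

test_that("post-blebbistatin concentric and eccentric have equal expected power", {
  b <- sample_bundle(seed = 23)
  trs <- generate_trials(b, default_protocols(reduced = TRUE), noise = FALSE,
                         components = "metabolic")
  post <- Filter(function(tr) tr$blebbistatin, trs)
  expect_equal(length(post), 2L)
  p <- vapply(post, function(tr) tr$measured_mean_power, numeric(1))
  expect_equal(p[1], p[2], tolerance = 1e-6)
})

test_that("fixtures write to disk with ground truth kept separate", {
  b <- sample_bundle(seed = 24)
  trs <- generate_trials(b, default_protocols(reduced = TRUE), noise = FALSE,
                         components = c("static", "metabolic"))
  dir <- withr::local_tempdir()
  mp <- write_fixtures(list(b), list(trs), dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_named(man, "bundle_01")
  gt <- read_parameters(file.path(dir, "bundle_01", "ground_truth.json"))
  expect_equal(gt$elastic$f_max_ce, b$pars$elastic$f_max_ce)
  # trial CSVs listed in the manifest exist
  files <- vapply(man$bundle_01$trials, function(x) x$file, character(1))
  expect_true(all(file.exists(file.path(dir, "bundle_01", files))))
})

test_that("force-decline ratio follows the exponential decline model", {
  # closed form check
  tau <- 240; T_tr <- 120; per <- 0.5
  r <- force_decline_ratio(tau, T_tr, per)
  md <- function(T) tau / T * (1 - exp(-T / tau))
  expect_equal(r, md(T_tr) / md(per))
  expect_lt(r, 1)
  expect_gt(r, 0.5)
  # no decline limit
  expect_equal(force_decline_ratio(1e9, T_tr, per), 1, tolerance = 1e-6)
})

test_that("parameter sets round-trip through JSON", {
  b <- sample_bundle(seed = 25)
  path <- withr::local_tempfile(fileext = ".json")
  write_parameters(b$pars, path)
  back <- read_parameters(path)
  expect_equal(back, b$pars, tolerance = 1e-12)
})
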