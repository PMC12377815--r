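test_that("rmse_rel matches closed forms and rejects degenerate input", {
  f_max <- 0.016
  t1 <- rep(0.002, 100); t2 <- rep(0.005, 300)
  # identical traces
  expect_identical(rmse_rel(list(t1, t2), list(t1, t2), f_max, 5e-4), 0)
  # constant offset delta on all traces -> 100 * delta / f_max
  d <- 1e-3
  expect_equal(rmse_rel(list(t1 + d, t2 + d), list(t1, t2), f_max, 5e-4),
               100 * d / f_max)
  expect_error(rmse_rel(list(), list(), f_max, 5e-4), ">= 1")
})

test_that("static fit recovers generating parameters and flags boundaries", {
  b <- sample_bundle(seed = 11)
  trs <- generate_trials(b, default_protocols(reduced = TRUE), noise = FALSE,
                         components = "static")
  sf <- fit_static(trs[[1]], b$pars, l_rest = b$l_rest)
  tr_el <- b$pars$elastic
  expect_equal(sf$elastic$f_max_ce, tr_el$f_max_ce, tolerance = 1e-4)
  expect_equal(sf$elastic$l_ce_opt, tr_el$l_ce_opt, tolerance = 1e-4)
  expect_equal(sf$elastic$see_slack, tr_el$see_slack, tolerance = 1e-4)
  expect_equal(sf$elastic$pee_shape, tr_el$pee_shape, tolerance = 1e-3)
  expect_lt(sf$rmse_pct, 1e-6)
  expect_false(any(sf$at_boundary))
  # data generated outside the constraint box: the l_ce_opt bound engages
  expect_warning(
    sf2 <- fit_static(trs[[1]], b$pars, l_rest = 0.8 * b$l_rest),
    "boundary")
  expect_true(sf2$at_boundary[["l_ce_opt"]])
})

test_that("static fit achieves low-percent RMSE under measurement noise", {
  b <- sample_bundle(seed = 12, force_noise_rel = 0.02)
  trs <- generate_trials(b, default_protocols(reduced = TRUE), noise = TRUE,
                         components = "static")
  sf <- fit_static(trs[[1]], b$pars, l_rest = b$l_rest)
  # 2% multiplicative-scale noise -> fit RMSE in the low-percent range
  expect_lt(sf$rmse_pct, 6)
  expect_gt(sf$rmse_pct, 0.1)
})

test_that("energetic fit recovers c1-c3 exactly on noiseless data", {
  b <- sample_bundle(seed = 13)
  trs <- generate_trials(b, default_protocols(reduced = TRUE), noise = FALSE,
                         components = "metabolic")
  ef <- fit_energetics(trs, b$pars)
  en <- b$pars$energetic
  expect_equal(ef$energetic$c1, en$c1, tolerance = 1e-6)
  expect_equal(ef$energetic$c2, en$c2, tolerance = 1e-6)
  expect_equal(ef$energetic$c3, en$c3, tolerance = 1e-10)
  expect_true(all(ef$identifiable))
  # the energetic stage never alters mechanical parameters
  expect_identical(ef$pars$elastic, b$pars$elastic)
  expect_identical(ef$pars$rates, b$pars$rates)
  expect_identical(ef$pars$activation, b$pars$activation)
})

test_that("energetic stage separation: post-blebbistatin trials alone give c3 only", {
  b <- sample_bundle(seed = 13)
  trs <- generate_trials(b, default_protocols(reduced = TRUE), noise = FALSE,
                         components = "metabolic")
  post <- Filter(function(tr) tr$blebbistatin, trs)
  ef <- fit_energetics(post, b$pars)
  expect_equal(ef$energetic$c3, b$pars$energetic$c3, tolerance = 1e-10)
  expect_true(is.na(ef$energetic$c1))
  expect_true(is.na(ef$energetic$c2))
  # no pre-blebbistatin trials -> must fail loudly
  pre <- Filter(function(tr) !tr$blebbistatin, trs)
  expect_error(fit_energetics(pre, b$pars), "post-blebbistatin")
})

test_that("a single eccentric pre-blebbistatin trial is fitted near-perfectly", {
  b <- sample_bundle(seed = 14)
  trs <- generate_trials(b, default_protocols(reduced = TRUE), noise = FALSE,
                         components = "metabolic")
  keep <- Filter(function(tr) {
    tr$blebbistatin || tr$condition == "eccentric"
  }, trs)
  ef <- suppressWarnings(fit_energetics(keep, b$pars))
  ecc_row <- ef$trials[!ef$trials$post, ]
  expect_equal(nrow(ecc_row), 1L)
  expect_lt(abs(ecc_row$rel_resid), 1e-8)
})

test_that("cross-validation bookkeeping: 1x1 matrix equals the own fit", {
  b <- sample_bundle(seed = 15)
  trs <- generate_trials(b, default_protocols(reduced = TRUE),
                         noise = FALSE,
                         components = c("force_frequency", "dynamic"))
  # a minimal 'fit' whose parameters are the truth: evaluate, don't optimize
  obj <- evaluate_rmse(b$pars, trs)
  m <- cross_validate(list(b$pars), list(trs))
  expect_identical(dim(m), c(1L, 1L))
  expect_identical(m[1, 1], obj)
  expect_error(cross_validate(list(b$pars), list()), "aligned")
})
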