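# Synthetic "animals" (fibre bundles) and trial suites with the
# statistical structure of the fibre-bundle experiments, so every pipeline
# stage is testable without laboratory data.

#' Sampling ranges for synthetic bundles
#'
#' Parameter ranges are anchored to the per-animal spreads reported for
#' mouse soleus fibre bundles: maximum CE force 12-24 mN, optimum CE length
#' 5.3-7.3 mm, tendon slack 2.1-2.9 mm, activation time constants
#' 0.022-0.090 s / 0.053-0.083 s, kappa 0.15-0.79, energetic weights
#' c1 0.086-0.38, c2 0.003-0.23 J kg^-1 m^-1, c3 48-340 W kg^-1. Rate
#' parameters are sampled log-uniformly around the reported central values.
#'
#' @param pee_interpretation `"pee_strain"` (default) samples the PEE shape
#'   parameter in \[0.6, 1.2\] so passive force at optimum is of order 1% of
#'   maximum force; `"table_raw"` samples the raw tabulated 0.16-1.00 range
#'   (whose symbol attribution in the source tables is ambiguous).
#' @return named list of `c(lo, hi)` ranges plus a `log` flag vector.
#' @export
bundle_ranges <- function(pee_interpretation = c("pee_strain", "table_raw")) {
  pee_interpretation <- match.arg(pee_interpretation)
  pee <- if (pee_interpretation == "pee_strain") c(0.6, 1.2) else c(0.16, 1.0)
  list(
    f_max_ce = c(12e-3, 24e-3), l_ce_opt = c(5.3e-3, 7.3e-3),
    see_slack = c(2.1e-3, 2.9e-3), pee_shape = pee,
    tau_act = c(0.022, 0.090), tau_deact = c(0.053, 0.083),
    kappa = c(0.15, 0.79),
    f1 = c(340, 1400), g2 = c(6e3, 2.6e4), g3 = c(200, 2000),
    c1 = c(0.086, 0.38), c2 = c(0.003, 0.23), c3 = c(48, 340),
    log = c(f1 = TRUE, g2 = TRUE, g3 = TRUE)
  )
}

#' Sample one synthetic bundle
#'
#' Draws a ground-truth parameter set from [bundle_ranges()] together with
#' the bundle's noise model: additive Gaussian force noise (as a fraction
#' of `f_max_ce`), multiplicative Gaussian noise on trial-mean metabolic
#' power, and a slow exponential within-trial force decline.
#'
#' @param seed integer seed; the bundle is fully determined by it.
#' @param ranges list from [bundle_ranges()].
#' @param force_noise_rel force noise s.d. relative to `f_max_ce`.
#' @param metabolic_cv coefficient of variation of measured mean power;
#'   the default 0.09 reproduces a repeated-measures RMS-about-mean of
#'   order 1-2 W kg^-1 at typical power levels.
#' @param decline_tau time constant (s) of the within-trial decline of
#'   effective maximum CE force.
#' @param trial_duration duration (s) of a metabolic trial (the full trial
#'   is never simulated; it only sets the force-decline ratio).
#' @return list of class `bundle_spec` with `pars` (ground truth), noise
#'   fields, `l_rest` and `seed`.
#' @export
sample_bundle <- function(seed = 1L, ranges = bundle_ranges(),
                          force_noise_rel = 0.01, metabolic_cv = 0.09,
                          decline_tau = 240, trial_duration = 120) {
  set.seed(seed)
  draw <- function(name) {
    r <- ranges[[name]]
    if (isTRUE(ranges$log[name])) exp(stats::runif(1, log(r[1]), log(r[2])))
    else stats::runif(1, r[1], r[2])
  }
  el <- elastic_parameters(
    f_max_ce = draw("f_max_ce"), l_ce_opt = draw("l_ce_opt"),
    see_slack = draw("see_slack"), pee_shape = draw("pee_shape"))
  ac <- activation_parameters(
    tau_act = draw("tau_act"), tau_deact = draw("tau_deact"),
    kappa = draw("kappa"))
  rt <- rate_parameters(f1 = draw("f1"), g2 = draw("g2"), g3 = draw("g3"))
  en <- energetic_parameters(c1 = draw("c1"), c2 = draw("c2"),
                             c3 = draw("c3"))
  pars <- mtc_parameters(elastic = el, activation = ac, rates = rt,
                         energetic = en)
  structure(list(pars = pars, l_rest = el$l_ce_opt,
                 force_noise_rel = force_noise_rel,
                 metabolic_cv = metabolic_cv, decline_tau = decline_tau,
                 trial_duration = trial_duration, seed = as.integer(seed)),
            class = "bundle_spec")
}

#' MTC length at which the bundle produces peak tetanic force
#' @keywords internal
optimum_mtc_length <- function(pars) {
  el <- pars$elastic
  # CE at optimum; SEE stretched by (approximately) the tetanic force
  el$l_ce_opt + el$see_slack * (1 + el$see_strain_at_fmax)
}

#' Within-trial force-decline ratio of the fixture decline model
#'
#' Effective maximum CE force decays as `exp(-t / tau)` through a trial;
#' the ratio of whole-trial mean force to first-contraction mean force is
#' then the ratio of the mean decay factors over the two spans.
#'
#' @param tau decline time constant (s).
#' @param trial_duration whole-trial duration (s).
#' @param cycle_duration first-contraction duration (s).
#' @return scalar in (0, 1\].
#' @export
force_decline_ratio <- function(tau, trial_duration, cycle_duration) {
  mean_decay <- function(T) tau / T * (1 - exp(-T / tau))
  r <- mean_decay(trial_duration) / mean_decay(cycle_duration)
  min(r, 1)
}

#' Default trial suite of a synthetic bundle
#'
#' Mirrors the measurement protocol: an isometric force-length series, an
#' isometric force-frequency series at optimum length, dynamic sinusoidal
#' contractions (amplitudes 0.1-0.5 mm, frequencies 0.5-4 Hz, 4-8 pulses
#' at 100 Hz), and metabolic trials (0.25 mm 2 Hz, 0.50 mm 2 Hz,
#' 0.25 mm 3 Hz; 5 pulses at 100 Hz; concentric and eccentric phasing;
#' pre- and post-blebbistatin, with one repeated pre-blebbistatin
#' condition).
#'
#' @param reduced logical: a smaller suite (fewer dynamic trials) for
#'   fast test runs.
#' @return list with components `fl_rel`, `force_frequency`, `dynamic`,
#'   `metabolic` describing the protocols.
#' @export
default_protocols <- function(reduced = FALSE) {
  dyn <- if (reduced) {
    list(list(amp = 0.25e-3, freq = 2, phase = "concentric", n_pulses = 5L),
         list(amp = 0.25e-3, freq = 2, phase = "eccentric", n_pulses = 5L))
  } else {
    list(list(amp = 0.25e-3, freq = 2, phase = "concentric", n_pulses = 5L),
         list(amp = 0.25e-3, freq = 2, phase = "eccentric", n_pulses = 5L),
         list(amp = 0.50e-3, freq = 2, phase = "concentric", n_pulses = 5L),
         list(amp = 0.10e-3, freq = 4, phase = "concentric", n_pulses = 4L),
         list(amp = 0.50e-3, freq = 1, phase = "eccentric", n_pulses = 8L))
  }
  met <- list(
    list(amp = 0.25e-3, freq = 2, phase = "concentric", bleb = FALSE, rep = 2L),
    list(amp = 0.50e-3, freq = 2, phase = "concentric", bleb = FALSE, rep = 1L),
    list(amp = 0.25e-3, freq = 3, phase = "concentric", bleb = FALSE, rep = 1L),
    list(amp = 0.25e-3, freq = 2, phase = "eccentric", bleb = FALSE, rep = 1L),
    list(amp = 0.25e-3, freq = 2, phase = "concentric", bleb = TRUE, rep = 1L),
    list(amp = 0.25e-3, freq = 2, phase = "eccentric", bleb = TRUE, rep = 1L))
  list(
    fl_rel = seq(0.80, 1.20, by = if (reduced) 0.08 else 0.05),
    force_frequency = list(list(rate = 30, n_pulses = 4L),
                           list(rate = 100, n_pulses = 8L)),
    dynamic = dyn,
    metabolic = met
  )
}

#' Generate the synthetic trial suite of one bundle
#'
#' Simulates every protocol with the bundle's ground-truth parameters and
#' applies the noise model: additive Gaussian force noise, multiplicative
#' Gaussian noise on mean metabolic power, and the within-trial force
#' decline (entering metabolic trials through their decline ratio).
#' Post-blebbistatin trial powers are generated from the calcium-pumping
#' term alone (cross-bridge cycling disabled, calcium handling intact), and
#' concentric/eccentric post-blebbistatin trials therefore have equal
#' expected power. Repeated conditions are duplicated with independent
#' noise.
#'
#' @param bundle `bundle_spec`.
#' @param protocols list from [default_protocols()].
#' @param noise logical; `FALSE` yields noiseless traces and powers.
#' @param components character subset of
#'   `c("static", "force_frequency", "dynamic", "metabolic")`.
#' @param options `sim_options` for the generating simulations.
#' @param sample_rate sampling rate (Hz).
#' @return list of `trial_record`s.
#' @export
generate_trials <- function(bundle, protocols = default_protocols(),
                            noise = TRUE,
                            components = c("static", "force_frequency",
                                           "dynamic", "metabolic"),
                            options = sim_options(), sample_rate = 2000) {
  stopifnot(inherits(bundle, "bundle_spec"))
  pars <- bundle$pars
  el <- pars$elastic
  set.seed(bundle$seed + 1000L)
  sd_force <- if (noise) bundle$force_noise_rel * el$f_max_ce else 0
  l_opt_mtc <- optimum_mtc_length(pars)
  trials <- list()

  if ("static" %in% components) {
    l_mtc <- el$see_slack + el$l_ce_opt * protocols$fl_rel
    fa <- static_force_length(l_mtc, pars, drive = 1) +
      stats::rnorm(length(l_mtc), 0, sd_force)
    fp <- static_force_length(l_mtc, pars, drive = 0) +
      stats::rnorm(length(l_mtc), 0, sd_force)
    trials[[length(trials) + 1L]] <- trial_record(
      trial_kind = "static_fl", condition = "isometric",
      fl_points = data.frame(l_mtc = l_mtc, f_active = fa, f_passive = fp),
      id = "static_fl")
  }

  if ("force_frequency" %in% components) {
    for (ff in protocols$force_frequency) {
      p <- movement_protocol(kind = "isometric", offset_length = l_opt_mtc,
                             n_pulses = ff$n_pulses, pulse_rate = ff$rate,
                             lead_in = 0.05, tail = 0.35)
      inp <- make_length_trajectory(p, sample_rate)
      sim <- simulate_mtc(inp, pars, options)
      trials[[length(trials) + 1L]] <- trial_record(
        input = inp,
        measured_force = sim$f_see + stats::rnorm(nrow(sim), 0, sd_force),
        trial_kind = "force_frequency", condition = "isometric",
        id = sprintf("ff_%gHz_%dp", ff$rate, ff$n_pulses))
    }
  }

  if ("dynamic" %in% components) {
    for (dn in protocols$dynamic) {
      p <- movement_protocol(kind = "sinusoid", amplitude = dn$amp,
                             frequency = dn$freq,
                             offset_length = l_opt_mtc,
                             stim_phase = dn$phase, n_cycles = 2L,
                             n_pulses = dn$n_pulses, lead_in = 0.1,
                             tail = 0.25)
      inp <- make_length_trajectory(p, sample_rate)
      sim <- simulate_mtc(inp, pars, options)
      trials[[length(trials) + 1L]] <- trial_record(
        input = inp,
        measured_force = sim$f_see + stats::rnorm(nrow(sim), 0, sd_force),
        trial_kind = "dynamic",
        condition = dn$phase,
        id = sprintf("dyn_%0.2fmm_%gHz_%s", 1e3 * dn$amp, dn$freq,
                     substr(dn$phase, 1, 3)))
    }
  }

  if ("metabolic" %in% components) {
    for (mt in protocols$metabolic) {
      per <- 1 / mt$freq
      p <- movement_protocol(kind = "sinusoid", amplitude = mt$amp,
                             frequency = mt$freq,
                             offset_length = l_opt_mtc,
                             stim_phase = mt$phase, n_cycles = 2L,
                             n_pulses = 5L, lead_in = 0.1, tail = 0.2)
      inp <- make_length_trajectory(p, sample_rate)
      centre <- 0.1 + if (mt$phase == "concentric") per / 2 else per
      window <- c(centre - per / 2, centre + per / 2)
      decline <- force_decline_ratio(bundle$decline_tau,
                                     bundle$trial_duration, per)
      sim <- simulate_mtc(inp, pars, options,
                          blebbistatin = mt$bleb,
                          force_decline_ratio = decline)
      sel <- sim$t >= window[1L] & sim$t <= window[2L]
      dur <- max(sim$t[sel]) - min(sim$t[sel])
      p_true <- trapz(sim$t[sel], sim$p_total[sel]) / dur
      for (k in seq_len(mt$rep)) {
        p_meas <- p_true *
          (if (noise) 1 + bundle$metabolic_cv * stats::rnorm(1) else 1)
        trials[[length(trials) + 1L]] <- trial_record(
          input = inp,
          measured_force = sim$f_see + stats::rnorm(nrow(sim), 0, sd_force),
          trial_kind = "metabolic", condition = mt$phase,
          blebbistatin = mt$bleb, measured_mean_power = p_meas,
          force_decline_ratio = decline,
          id = sprintf("met_%0.2fmm_%gHz_%s%s_r%d", 1e3 * mt$amp, mt$freq,
                       substr(mt$phase, 1, 3),
                       if (mt$bleb) "_bleb" else "", k),
          metadata = list(avg_window = window))
      }
    }
  }
  trials
}

#' Sample a cohort of synthetic bundles
#'
#' @param n_bundles number of bundles (default 9, mirroring the cohort
#'   size of the emulated experiment).
#' @param seed master seed; bundle i uses `seed * 1000 + i`.
#' @param ranges sampling ranges, see [bundle_ranges()].
#' @param ... forwarded to [sample_bundle()].
#' @return list of `bundle_spec`s.
#' @export
make_cohort <- function(n_bundles = 9L, seed = 1L,
                        ranges = bundle_ranges(), ...) {
  base <- (as.numeric(seed) %% 2e6) * 1000
  lapply(seq_len(n_bundles), function(i) {
    sample_bundle(seed = as.integer(base + i), ranges = ranges, ...)
  })
}

#' Write a cohort's fixtures to disk
#'
#' Writes per-trial CSVs, a manifest JSON (trial paths and labels) and a
#' separate ground-truth JSON per bundle, so fitting code can be run blind
#' to the truth.
#'
#' @param cohort list of `bundle_spec`s.
#' @param trials_by_bundle list of trial lists, aligned with `cohort`.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_fixtures <- function(cohort, trials_by_bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (i in seq_along(cohort)) {
    bdir <- file.path(dir, sprintf("bundle_%02d", i))
    dir.create(bdir, showWarnings = FALSE)
    write_parameters(cohort[[i]]$pars,
                     file.path(bdir, "ground_truth.json"))
    rows <- list()
    for (tr in trials_by_bundle[[i]]) {
      if (tr$trial_kind == "static_fl") {
        fn <- file.path(bdir, "static_fl.csv")
        utils::write.csv(tr$fl_points, fn, row.names = FALSE)
        rows[[length(rows) + 1L]] <- list(id = tr$id, kind = tr$trial_kind,
                                          file = basename(fn))
      } else {
        fn <- file.path(bdir, paste0(tr$id, ".csv"))
        utils::write.csv(
          data.frame(t = tr$input$t, l_mtc = tr$input$l_mtc,
                     stim = tr$input$stim, force = tr$measured_force),
          fn, row.names = FALSE)
        rows[[length(rows) + 1L]] <- list(
          id = tr$id, kind = tr$trial_kind, condition = tr$condition,
          blebbistatin = tr$blebbistatin,
          measured_mean_power = tr$measured_mean_power,
          force_decline_ratio = tr$force_decline_ratio,
          file = basename(fn))
      }
    }
    manifest[[sprintf("bundle_%02d", i)]] <-
      list(seed = cohort[[i]]$seed, trials = rows)
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}
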