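# Assembles the constitutive relations into an integrable state-space
# system and runs trials through the compiled integrator.

#' Simulation options
#'
#' @param rtol relative tolerance of the adaptive integrator.
#' @param atol absolute tolerance (scaled by each state's typical size).
#' @param max_steps step budget before the integrator aborts.
#' @param regrid_threshold node drift (normalized bond lengths) that
#'   triggers re-interpolation onto the canonical grid.
#' @param boundary_tol attached fraction at the grid ends above which the
#'   simulation aborts with a re-grid-overflow error.
#' @param beta residual feedback gain (1/s) on the force-balance quasi-state;
#'   0 integrates the differentiated balance without feedback.
#' @param k_reg_rel stiffness regularization for the quasi-state rate,
#'   relative to `f_max_ce / l_ce_opt`.
#' @return list of class `sim_options`.
#' @export
sim_options <- function(rtol = 1e-6, atol = 1e-9, max_steps = 5e6,
                        regrid_threshold = 0.25, boundary_tol = 1e-3,
                        beta = 0, k_reg_rel = 1e-6) {
  structure(list(rtol = rtol, atol = atol, max_steps = max_steps,
                 regrid_threshold = regrid_threshold,
                 boundary_tol = boundary_tol, beta = beta,
                 k_reg_rel = k_reg_rel), class = "sim_options")
}

#' Flatten a parameter set for the compiled core
#' @keywords internal
model_flat <- function(pars, options, mode, blebbistatin = FALSE,
                       force_decline_ratio = 1,
                       m1_iso = first_moment_norm(pars)) {
  el <- pars$elastic; ac <- pars$activation; en <- pars$energetic
  dc <- list(
    c_see = el$f_max_ce / (el$see_strain_at_fmax * el$see_slack)^2,
    pee_slack = el$pee_slack_rel * el$l_ce_opt
  )
  dc$c_pee <- el$f_max_ce / (el$pee_shape * dc$pee_slack)^2
  n_sarc <- el$l_ce_opt / pars$scale$s_opt
  c_u <- 2 * n_sarc * pars$scale$h
  c(el$f_max_ce, el$l_ce_opt, el$ce_shape, el$see_slack, dc$c_see,
    dc$pee_slack, dc$c_pee,
    ac$tau_act, ac$tau_deact, ac$kappa, ac$n_coop, ac$q_min,
    c_u, el$f_max_ce / m1_iso, m1_iso,
    en$c1, en$c2, en$c3, en$split_x, pars$scale$h * n_sarc / m1_iso,
    force_decline_ratio, as.numeric(blebbistatin),
    options$beta, options$k_reg_rel * el$f_max_ce / el$l_ce_opt,
    mode)
}

#' Consistent initial state for a trial
#'
#' Resting muscle: gamma = 0, the distribution at the resting fixed point
#' for the floor active state, and `l_ce` solving the static force balance
#' `F_see(l_mtc - l_ce) = F_ce + F_pee(l_ce)` by root finding, to a
#' residual below `1e-10 * f_max_ce`.
#'
#' @param l_mtc0 MTC length at t = 0 (m).
#' @param pars `mtc_parameters`.
#' @return list of class `mtc_state` with `gamma`, `l_ce`, `distribution`.
#' @export
initialize_state <- function(l_mtc0, pars) {
  el <- pars$elastic
  if (!is.finite(l_mtc0) || l_mtc0 <= 0)
    stop("l_mtc0 must be positive and finite", call. = FALSE)
  m1_iso <- first_moment_norm(pars)
  q0 <- pars$activation$q_min
  balance <- function(l_ce) {
    drive <- q0 * isometric_force_length(l_ce / el$l_ce_opt, el$ce_shape)
    see_force(l_mtc0 - l_ce, pars) - el$f_max_ce * drive -
      pee_force(l_ce, pars)
  }
  lo <- 1e-4 * el$l_ce_opt
  hi <- l_mtc0 - 1e-12
  f_lo <- balance(lo); f_hi <- balance(hi)
  if (f_lo < 0 || f_hi > 0) {
    if (abs(f_hi) < 1e-10 * el$f_max_ce) {
      l_ce0 <- hi
    } else {
      stop("no consistent initial CE length in (0, l_mtc0): invalid geometry",
           call. = FALSE)
    }
  } else {
    l_ce0 <- stats::uniroot(balance, c(lo, hi), tol = 1e-14)$root
    # polish by bisection until the force residual is tight
    for (i in 1:60) {
      if (abs(balance(l_ce0)) < 1e-11 * el$f_max_ce) break
      step <- balance(l_ce0) /
        (see_stiffness(l_mtc0 - l_ce0, pars) + pee_stiffness(l_ce0, pars) +
           1e-6 * el$f_max_ce / el$l_ce_opt)
      cand <- l_ce0 + step
      if (cand <= lo || cand >= hi) break
      l_ce0 <- cand
    }
  }
  drive0 <- q0 * isometric_force_length(l_ce0 / el$l_ce_opt, el$ce_shape)
  d0 <- xb_steady_state(pars, drive = drive0)
  structure(list(gamma = 0, l_ce = l_ce0, distribution = d0),
            class = "mtc_state")
}

#' Simulate one trial of the muscle-tendon complex
#'
#' Integrates `{gamma, n(x), l_ce}` over the span of the input, with the
#' MTC length interpolated by a monotone cubic spline and stimulation held
#' piecewise constant between its block-pulse edges. Output is produced on
#' the input time grid (optionally thinned).
#'
#' @param input `simulation_input`.
#' @param pars `mtc_parameters`.
#' @param options `sim_options`.
#' @param state optional initial `mtc_state`; default [initialize_state()]
#'   at the first input length.
#' @param blebbistatin zero the cross-bridge power terms (mechanics
#'   unaffected: the flag models disabled cross-bridge *cost* accounting for
#'   post-blebbistatin energetic trials).
#' @param force_decline_ratio within-trial force decline scaling applied to
#'   the cross-bridge power terms, in (0, 1].
#' @param output_every report every k-th input sample (default 1).
#' @return `mtc_simulation`: a data.frame of time series (forces, lengths,
#'   activation states, distribution moments, metabolic powers, mechanical
#'   power) with the final distribution, diagnostics and inputs attached as
#'   attributes.
#' @export
simulate_mtc <- function(input, pars, options = sim_options(), state = NULL,
                         blebbistatin = FALSE, force_decline_ratio = 1,
                         output_every = 1L) {
  stopifnot(inherits(input, "simulation_input"),
            inherits(pars, "mtc_parameters"))
  if (force_decline_ratio <= 0 || force_decline_ratio > 1)
    stop("force_decline_ratio must lie in (0, 1]", call. = FALSE)
  if (is.null(state)) state <- initialize_state(input$l_mtc[1L], pars)
  run_core(input, pars, options, state, mode = 0L,
           blebbistatin = blebbistatin,
           force_decline_ratio = force_decline_ratio,
           output_every = output_every)
}

#' Simulate with prescribed contractile element length
#'
#' Fibre-level mode: `l_ce(t)` is imposed directly (no elastic elements),
#' and only `{gamma, n(x)}` are integrated. Useful for isokinetic ramps and
#' for validating the distribution solver in isolation.
#'
#' @param input `simulation_input` whose `l_mtc` column is interpreted as
#'   the imposed CE length.
#' @inheritParams simulate_mtc
#' @return `mtc_simulation` (force-balance columns are `NA`).
#' @export
simulate_ce <- function(input, pars, options = sim_options(), state = NULL,
                        blebbistatin = FALSE, force_decline_ratio = 1,
                        output_every = 1L) {
  stopifnot(inherits(input, "simulation_input"),
            inherits(pars, "mtc_parameters"))
  if (is.null(state)) {
    q0 <- pars$activation$q_min
    drive0 <- q0 * isometric_force_length(
      input$l_mtc[1L] / pars$elastic$l_ce_opt, pars$elastic$ce_shape)
    state <- structure(list(gamma = 0, l_ce = input$l_mtc[1L],
                            distribution = xb_steady_state(pars, drive0)),
                       class = "mtc_state")
  }
  run_core(input, pars, options, state, mode = 1L,
           blebbistatin = blebbistatin,
           force_decline_ratio = force_decline_ratio,
           output_every = output_every)
}

run_core <- function(input, pars, options, state, mode, blebbistatin,
                     force_decline_ratio, output_every) {
  t <- input$t
  dt <- 1 / input$sample_rate
  m1_iso <- first_moment_norm(pars)
  mf <- model_flat(pars, options, mode, blebbistatin, force_decline_ratio,
                   m1_iso)
  slopes <- monotone_slopes(t, input$l_mtc)
  rt <- rate_table(pars, margin = options$regrid_threshold + 0.35)
  x0 <- xb_grid(pars)
  # distribution must arrive on the canonical grid
  d <- state$distribution
  if (length(d$x) != length(x0) || max(abs(d$x - x0)) > 1e-12) {
    n0 <- stats::approx(d$x, d$n, xout = x0, yleft = 0, yright = 0)$y
  } else n0 <- d$n

  out_idx <- seq(1L, length(t), by = as.integer(output_every))
  if (out_idx[length(out_idx)] != length(t))
    out_idx <- c(out_idx, length(t))
  edges <- as.numeric(rbind(input$pulse_times,
                            input$pulse_times + input$pulse_width))
  edges <- sort(edges[edges > t[1L] & edges < t[length(t)]])
  check <- sort(unique(c(t[out_idx], edges)))
  is_out <- as.integer(check %in% t[out_idx])

  res <- .sim_core(c(t[1L], dt), input$l_mtc, slopes, edges, check, is_out,
                   x0, n0, state$gamma, state$l_ce, mf,
                   c(rt$x0, rt$dx), rt$f, rt$g, rt$fp, rt$gp,
                   c(options$rtol, options$atol, options$max_steps,
                     options$regrid_threshold, options$boundary_tol))
  diag <- res$diagnostics
  if (diag$status != 0) {
    msg <- if (diag$status == 2) {
      "distribution reached the grid boundary (re-grid overflow)"
    } else "integrator exceeded its step budget"
    stop(sprintf("simulation failed at t = %.4g s: %s", diag$t_reached, msg),
         call. = FALSE)
  }
  df <- as.data.frame(res$out)
  # mechanical power delivered by the MTC on the environment
  if (mode == 0L) {
    dldt <- hermite_eval(df$t, t, input$l_mtc, slopes, deriv = 1L)
    df$p_mech <- -df$f_see * dldt
  } else {
    dldt <- hermite_eval(df$t, t, input$l_mtc, slopes, deriv = 1L)
    df$p_mech <- -df$f_ce * dldt
  }
  xs <- x0 + res$shift_final
  structure(df,
            final_state = structure(
              list(gamma = res$gamma_final, l_ce = res$lce_final,
                   distribution = xb_distribution(xs, pmin(pmax(res$n_final, 0), 1))),
              class = "mtc_state"),
            parameters = pars, options = options, input = input,
            mode = mode, diagnostics = diag,
            class = c("mtc_simulation", "data.frame"))
}

#' Summarize a work-loop simulation
#'
#' Integrates work and metabolic energy over a time window (default the
#' full record): MTC work, CE work, cycle-mean metabolic powers, and the
#' mechanical efficiency (external MTC work divided by metabolic energy,
#' using the reference muscle mass to convert per-kg powers to watts).
#'
#' @param object `mtc_simulation`.
#' @param window `c(t_start, t_end)` in seconds, or `NULL` for the whole
#'   record.
#' @param ... unused.
#' @return named list of summary scalars.
#' @export
summary.mtc_simulation <- function(object, window = NULL, ...) {
  df <- object
  if (!is.null(window)) {
    df <- df[df$t >= window[1L] & df$t <= window[2L], , drop = FALSE]
  }
  pars <- attr(object, "parameters")
  mass <- pars$energetic$muscle_mass_norm
  w_mtc <- trapz(df$t, df$p_mech)
  # CE work from the CE force and CE velocity (central differences)
  nt <- nrow(df)
  dlce <- numeric(nt)
  dlce[2:(nt - 1L)] <- (df$l_ce[3:nt] - df$l_ce[1:(nt - 2L)]) /
    (df$t[3:nt] - df$t[1:(nt - 2L)])
  dlce[1L] <- (df$l_ce[2L] - df$l_ce[1L]) / (df$t[2L] - df$t[1L])
  dlce[nt] <- (df$l_ce[nt] - df$l_ce[nt - 1L]) / (df$t[nt] - df$t[nt - 1L])
  w_ce <- trapz(df$t, -df$f_ce * dlce)
  e_met <- trapz(df$t, df$p_total) * mass
  dur <- df$t[length(df$t)] - df$t[1L]
  list(
    duration = dur,
    work_mtc = w_mtc, work_ce = w_ce,
    mean_p_cb = trapz(df$t, df$p_cb_low + df$p_cb_high) / dur,
    mean_p_act = trapz(df$t, df$p_act) / dur,
    mean_p_total = trapz(df$t, df$p_total) / dur,
    metabolic_energy = e_met,
    efficiency = if (e_met > 0) w_mtc / e_met else NA_real_,
    max_force = max(df$f_ce),
    max_residual = attr(object, "diagnostics")$max_residual
  )
}

#' @export
print.mtc_simulation <- function(x, ...) {
  diag <- attr(x, "diagnostics")
  cat(sprintf("MTC simulation: %d samples over %.3g s\n", nrow(x),
              x$t[nrow(x)] - x$t[1L]))
  cat(sprintf("  peak CE force %.3g mN | steps %d | re-grids %d\n",
              1e3 * max(x$f_ce), as.integer(diag$n_steps),
              as.integer(diag$n_regrids)))
  if (!is.na(diag$max_residual))
    cat(sprintf("  max |force-balance residual| %.2e x F_max\n",
                diag$max_residual))
  invisible(x)
}

#' Write a simulation result to CSV (plus a summary JSON)
#'
#' @param sim `mtc_simulation`.
#' @param path CSV path; a `.json` summary is written alongside.
#' @export
write_result_csv <- function(sim, path) {
  utils::write.csv(as.data.frame(sim)[, c(
    "t", "l_mtc", "stim", "f_see", "f_ce", "l_ce", "gamma", "q",
    "p_cb_low", "p_cb_high", "p_act", "p_total")], path, row.names = FALSE)
  s <- summary(sim)
  jsonlite::write_json(s, sub("\\.csv$", "_summary.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
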