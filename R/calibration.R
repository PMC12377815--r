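# Three-stage parameter estimation (static elastic properties, rate and
# activation dynamics, energetic coefficients) and the cross-validation
# harness. Stage ordering is enforced by the interfaces: the dynamic stage
# consumes a static fit, the energetic stage consumes mechanical parameters
# and never alters them.

#' A single experimental (or synthetic) trial
#'
#' @param input `simulation_input` (not used for `static_fl` trials).
#' @param measured_force sampled force trace (N) aligned with the input
#'   grid.
#' @param trial_kind one of `"static_fl"`, `"force_frequency"`,
#'   `"dynamic"`, `"metabolic"`.
#' @param condition `"concentric"`, `"eccentric"` or `"isometric"`.
#' @param blebbistatin logical flag.
#' @param measured_mean_power time-averaged metabolic power (W kg^-1);
#'   required for (and only allowed on) metabolic trials.
#' @param force_decline_ratio within-trial mean force relative to the first
#'   contraction, in (0, 1].
#' @param fl_points for `static_fl` trials: data.frame with `l_mtc`,
#'   `f_active`, `f_passive` (N).
#' @param id trial label.
#' @param metadata free-form list (e.g. averaging window).
#' @return list of class `trial_record`.
#' @export
trial_record <- function(input = NULL, measured_force = NULL,
                         trial_kind = c("dynamic", "force_frequency",
                                        "metabolic", "static_fl"),
                         condition = c("isometric", "concentric",
                                       "eccentric"),
                         blebbistatin = FALSE, measured_mean_power = NULL,
                         force_decline_ratio = 1, fl_points = NULL,
                         id = NULL, metadata = list()) {
  trial_kind <- match.arg(trial_kind)
  condition <- match.arg(condition)
  if (trial_kind == "metabolic") {
    if (is.null(measured_mean_power))
      stop("metabolic trials need measured_mean_power", call. = FALSE)
  } else if (!is.null(measured_mean_power)) {
    stop("measured_mean_power is only allowed on metabolic trials",
         call. = FALSE)
  }
  if (trial_kind == "static_fl") {
    if (is.null(fl_points) || !all(c("l_mtc", "f_active", "f_passive") %in%
                                   names(fl_points)))
      stop("static_fl trials need fl_points(l_mtc, f_active, f_passive)",
           call. = FALSE)
  } else {
    if (is.null(input)) stop("sampled trials need an input", call. = FALSE)
    if (!is.null(measured_force) &&
        length(measured_force) != length(input$t))
      stop("measured_force must align with the input grid", call. = FALSE)
  }
  if (force_decline_ratio <= 0 || force_decline_ratio > 1)
    stop("force_decline_ratio must lie in (0, 1]", call. = FALSE)
  structure(list(input = input, measured_force = measured_force,
                 trial_kind = trial_kind, condition = condition,
                 blebbistatin = blebbistatin,
                 measured_mean_power = measured_mean_power,
                 force_decline_ratio = force_decline_ratio,
                 fl_points = fl_points, id = id, metadata = metadata),
            class = "trial_record")
}

#' Relative RMSE cost across trials
#'
#' Root of the duration-weighted mean squared force difference pooled over
#' all trials, expressed as a percentage of maximum isometric CE force:
#' `100/f_max * sqrt( sum_i dt_i sum_k e_ik^2 / sum_i T_i )`. The
#' alternative `"equal"` weighting averages each trial's mean square with
#' equal weight regardless of duration.
#'
#' @param model_forces list of per-trial model force vectors (N).
#' @param measured_forces list of per-trial measured force vectors (N).
#' @param f_max_ce maximum isometric CE force (N).
#' @param dt per-trial sample interval (s); scalar or vector.
#' @param weighting `"duration"` (default) or `"equal"`.
#' @return percentage (scalar).
#' @export
rmse_rel <- function(model_forces, measured_forces, f_max_ce, dt,
                     weighting = c("duration", "equal")) {
  weighting <- match.arg(weighting)
  if (!is.list(model_forces)) model_forces <- list(model_forces)
  if (!is.list(measured_forces)) measured_forces <- list(measured_forces)
  n <- length(model_forces)
  if (n == 0L || length(measured_forces) != n)
    stop("need >= 1 aligned trial pair", call. = FALSE)
  dt <- rep_len(dt, n)
  ss <- 0; tt <- 0; msq <- numeric(n)
  for (i in seq_len(n)) {
    e <- model_forces[[i]] - measured_forces[[i]]
    if (length(e) == 0L) stop("empty trial", call. = FALSE)
    ss <- ss + dt[i] * sum(e^2)
    tt <- tt + dt[i] * length(e)
    msq[i] <- mean(e^2)
  }
  if (weighting == "duration") 100 * sqrt(ss / tt) / f_max_ce
  else 100 * sqrt(mean(msq)) / f_max_ce
}

#' Static force at a given MTC length
#'
#' Steady-state force of the assembled MTC at constant length and constant
#' drive: solves the force balance
#' `F_see(l_mtc - l_ce) = drive * f_max_ce * F_isom(l_ce) + F_pee(l_ce)`
#' for `l_ce` and returns the SEE (tendon) force. With `drive = 1` this is
#' the fused-tetanus plateau force used for force-length characterization;
#' with `drive = 0` the passive force.
#'
#' @param l_mtc MTC length(s) (m).
#' @param pars `mtc_parameters`.
#' @param drive constant drive in \[0, 1\].
#' @return force(s) (N).
#' @export
static_force_length <- function(l_mtc, pars, drive = 1) {
  el <- pars$elastic
  vapply(l_mtc, function(lm) {
    balance <- function(l_ce) {
      see_force(lm - l_ce, pars) -
        drive * el$f_max_ce *
          isometric_force_length(l_ce / el$l_ce_opt, el$ce_shape) -
        pee_force(l_ce, pars)
    }
    lo <- 1e-4 * el$l_ce_opt; hi <- lm - 1e-12
    if (balance(hi) >= 0) return(0)       # everything slack
    if (balance(lo) <= 0) return(see_force(lm - lo, pars))
    l_ce <- stats::uniroot(balance, c(lo, hi), tol = 1e-13)$root
    see_force(lm - l_ce, pars)
  }, numeric(1))
}

#' Stage 1: fit static elastic and force-length parameters
#'
#' Fits `f_max_ce`, `l_ce_opt`, `see_slack` and the PEE shape parameter to
#' measured active and passive force-length points by minimizing the joint
#' sum of squared differences. `l_ce_opt` is constrained to
#' `[0.9, 1.1] * l_rest` (fibre length at rest). The CE shape, SEE strain
#' and relative PEE slack are shared constants taken from `fixed`.
#'
#' @param fl_trials a `trial_record` of kind `static_fl`, or a list of them
#'   (points are pooled).
#' @param fixed `mtc_parameters` supplying the shared constants.
#' @param l_rest fibre length at rest (m), defining the `l_ce_opt`
#'   constraint box.
#' @return list of class `static_fit`: fitted `elastic` parameters, the
#'   updated full parameter set `pars`, `rmse_pct` (RMSE as % of fitted
#'   `f_max_ce`), `at_boundary` flags and optimizer diagnostics.
#' @export
fit_static <- function(fl_trials, fixed, l_rest) {
  if (inherits(fl_trials, "trial_record")) fl_trials <- list(fl_trials)
  pts <- do.call(rbind, lapply(fl_trials, function(tr) {
    stopifnot(tr$trial_kind == "static_fl")
    tr$fl_points
  }))
  if (nrow(pts) < 4L)
    stop("need >= 4 force-length points", call. = FALSE)
  f_scale <- max(pts$f_active)
  l_scale <- l_rest

  build <- function(th) {
    # th: scaled (f_max, l_opt, see_slack, pee_shape)
    el <- fixed$elastic
    elastic_parameters(
      f_max_ce = th[1L] * f_scale, l_ce_opt = th[2L] * l_scale,
      ce_shape = el$ce_shape, see_slack = th[3L] * l_scale,
      see_strain_at_fmax = el$see_strain_at_fmax,
      pee_slack_rel = el$pee_slack_rel, pee_shape = th[4L])
  }
  obj <- function(th) {
    p <- fixed
    p$elastic <- build(th)
    ra <- static_force_length(pts$l_mtc, p, drive = 1) - pts$f_active
    rp <- static_force_length(pts$l_mtc, p, drive = 0) - pts$f_passive
    sum(ra^2 + rp^2) / f_scale^2
  }
  i_pk <- which.max(pts$f_active)
  th0 <- c(1.0, 1.0,
           max(0.3, (pts$l_mtc[i_pk] - l_rest * 1.02) / l_scale), 1.0)
  lower <- c(0.2, 0.9, 0.05, 0.05)
  upper <- c(3.0, 1.1, max(pts$l_mtc) / l_scale - 0.3, 8.0)
  th0 <- pmin(pmax(th0, lower + 1e-3), upper - 1e-3)
  fit <- stats::optim(th0, obj, method = "L-BFGS-B", lower = lower,
                      upper = upper,
                      control = list(maxit = 400, factr = 1e1,
                                     ndeps = rep(1e-7, 4)))
  # Nelder-Mead polish inside the box
  pol <- stats::optim(fit$par, function(th) {
    if (any(th < lower | th > upper)) return(1e6 + sum(th^2))
    obj(th)
  }, method = "Nelder-Mead",
  control = list(maxit = 500, reltol = 1e-14))
  if (pol$value < fit$value) fit <- pol
  el_fit <- build(fit$par)
  pars <- fixed
  pars$elastic <- el_fit
  n_pts <- 2L * nrow(pts)
  rmse_pct <- 100 * sqrt(fit$value * f_scale^2 / n_pts) / el_fit$f_max_ce
  at_bound <- abs(fit$par - lower) < 1e-6 | abs(fit$par - upper) < 1e-6
  names(at_bound) <- c("f_max_ce", "l_ce_opt", "see_slack", "pee_shape")
  if (any(at_bound))
    warning("static fit ended on a constraint boundary: ",
            paste(names(at_bound)[at_bound], collapse = ", "),
            call. = FALSE)
  structure(list(elastic = el_fit, pars = pars, rmse_pct = rmse_pct,
                 at_boundary = at_bound, objective = fit$value,
                 convergence = fit$convergence, l_rest = l_rest),
            class = "static_fit")
}

#' Evaluate the dynamic cost of a parameter set on a set of trials
#'
#' Simulates every sampled trial and returns the pooled [rmse_rel()]
#' between the model SEE (tendon) force and the measured force. This is
#' the objective of the dynamic fitting stage and the quantity tabulated
#' by [cross_validate()]; it is deterministic given parameters, trials and
#' options.
#'
#' @param pars `mtc_parameters`.
#' @param trials list of `trial_record`s (kinds `dynamic` and
#'   `force_frequency`).
#' @param options `sim_options`.
#' @param weighting passed to [rmse_rel()].
#' @return percentage (scalar).
#' @export
evaluate_rmse <- function(pars, trials, options = sim_options(),
                          weighting = "duration") {
  model <- list(); meas <- list(); dts <- numeric(0)
  for (tr in trials) {
    if (tr$trial_kind %in% c("static_fl")) next
    sim <- simulate_mtc(tr$input, pars, options)
    model[[length(model) + 1L]] <- sim$f_see
    meas[[length(meas) + 1L]] <- tr$measured_force
    dts <- c(dts, 1 / tr$input$sample_rate)
  }
  rmse_rel(model, meas, pars$elastic$f_max_ce, dts, weighting = weighting)
}

#' Stage 2: fit rate and activation parameters
#'
#' Fits `f1`, `g2`, `g3` (log-scale), `tau_act`, `tau_deact` and `kappa`
#' simultaneously to the dynamic sinusoidal trials and the isometric
#' force-frequency trials by minimizing [rmse_rel()], using bounded
#' quasi-Newton optimization from several randomly chosen starting points.
#' `g1` stays fixed (no isometric energy-rate data identify it) and the
#' static parameters are taken from stage 1 unchanged. Cooperativity
#' `n_coop` is held fixed by default.
#'
#' @param trials list of `trial_record`s (dynamic + force_frequency).
#' @param static_fit a `static_fit` (or an `mtc_parameters` to use
#'   directly).
#' @param n_starts number of random starts (default 5).
#' @param seed RNG seed for start sampling.
#' @param bounds named list of `c(lo, hi)` per parameter; defaults span the
#'   physiological ranges of the fixture generator.
#' @param options `sim_options` used for every objective evaluation.
#' @param maxit quasi-Newton iteration budget per start.
#' @param polish_maxit Nelder-Mead polish budget applied to the best start.
#' @param weighting passed to [rmse_rel()].
#' @return list of class `dynamic_fit`: fitted `pars`, `objective`
#'   (rmse_rel %), a per-start table, seed and settings.
#' @export
fit_dynamic <- function(trials, static_fit, n_starts = 5L, seed = 1L,
                        bounds = NULL, options = sim_options(),
                        maxit = 30L, polish_maxit = 150L,
                        weighting = "duration") {
  pars0 <- if (inherits(static_fit, "static_fit")) static_fit$pars
           else static_fit
  if (is.null(bounds)) {
    bounds <- list(f1 = c(200, 2500), g2 = c(3e3, 5e4), g3 = c(80, 5e3),
                   tau_act = c(0.010, 0.12), tau_deact = c(0.025, 0.15),
                   kappa = c(0.08, 0.85))
  }
  lower <- c(log(bounds$f1[1]), log(bounds$g2[1]), log(bounds$g3[1]),
             bounds$tau_act[1], bounds$tau_deact[1], bounds$kappa[1])
  upper <- c(log(bounds$f1[2]), log(bounds$g2[2]), log(bounds$g3[2]),
             bounds$tau_act[2], bounds$tau_deact[2], bounds$kappa[2])
  build <- function(th) {
    p <- pars0
    p$rates <- rate_parameters(f1 = exp(th[1L]), g1 = p$rates$g1,
                               g2 = exp(th[2L]), g3 = exp(th[3L]),
                               smooth_width = p$rates$smooth_width)
    p$activation <- activation_parameters(
      tau_act = th[4L], tau_deact = th[5L], kappa = th[6L],
      n_coop = p$activation$n_coop, q_min = p$activation$q_min)
    p
  }
  obj <- function(th) {
    if (any(!is.finite(th))) return(1e6)
    evaluate_rmse(build(th), trials, options, weighting)
  }
  set.seed(seed)
  starts <- replicate(n_starts, lower + stats::runif(6) * (upper - lower))
  res <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    th0 <- starts[, s]
    fit <- tryCatch(
      stats::optim(th0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = maxit, factr = 1e7,
                                  ndeps = rep(1e-4, 6))),
      error = function(e) list(par = th0, value = obj(th0),
                               convergence = 99L, message = conditionMessage(e)))
    res[[s]] <- fit
  }
  vals <- vapply(res, function(r) r$value, numeric(1))
  if (all(vals >= 1e6))
    stop("dynamic fit: all starts failed to converge", call. = FALSE)
  best <- which.min(vals)
  th_best <- res[[best]]$par
  if (polish_maxit > 0L) {
    pol <- stats::optim(th_best, function(th) {
      if (any(th < lower | th > upper)) return(1e6)
      obj(th)
    }, method = "Nelder-Mead",
    control = list(maxit = polish_maxit, reltol = 1e-10))
    if (pol$value <= vals[best]) {
      th_best <- pol$par
      res[[best]]$value <- pol$value
      res[[best]]$par <- th_best
    }
  }
  pars_fit <- build(th_best)
  objective <- evaluate_rmse(pars_fit, trials, options, weighting)
  start_tab <- data.frame(
    start = seq_len(n_starts),
    objective = vapply(res, function(r) r$value, numeric(1)),
    convergence = vapply(res, function(r) as.integer(r$convergence %||% 0L),
                         integer(1)))
  structure(list(pars = pars_fit, objective = objective,
                 starts = start_tab, best_start = best, seed = seed,
                 bounds = bounds, options = options, weighting = weighting,
                 n_trials = length(trials)),
            class = "dynamic_fit")
}

#' Stage 3: fit the energetic coefficients
#'
#' For each metabolic trial, simulates the first contraction with the
#' (already fitted, here untouched) mechanical parameters, extracts the
#' time-averaged unit-coefficient cross-bridge power terms (scaled by the
#' trial's force-decline ratio) and the mean free calcium. `c3` is solved
#' first by least squares on the post-blebbistatin trials alone (whose
#' cross-bridge integrals are zeroed); the known `c3 * mean(gamma)` term is
#' then subtracted from the pre-blebbistatin powers and `(c1, c2)` solved
#' by the Moore-Penrose pseudo-inverse.
#'
#' @param met_trials list of metabolic `trial_record`s; each needs
#'   `metadata$avg_window = c(t0, t1)` delimiting the first contraction.
#' @param pars_mech `mtc_parameters` with fitted mechanical parameters.
#' @param options `sim_options`.
#' @param rank_tol relative singular-value threshold below which `(c1, c2)`
#'   are declared unidentifiable.
#' @return list of class `energetic_fit`: `energetic` parameters (with
#'   `c1`/`c2` `NA` when not identifiable or no pre-blebbistatin trials),
#'   updated `pars`, per-trial table, and `rmse_pred_pct` (RMS of relative
#'   prediction error on pre-blebbistatin trials, %).
#' @export
fit_energetics <- function(met_trials, pars_mech, options = sim_options(),
                           rank_tol = 1e-10) {
  stopifnot(length(met_trials) >= 1L)
  post <- vapply(met_trials, function(tr) isTRUE(tr$blebbistatin), logical(1))
  if (!any(post))
    stop("need >= 1 post-blebbistatin trial to identify c3", call. = FALSE)
  pars_unit <- pars_mech
  pars_unit$energetic <- energetic_parameters(
    c1 = 1, c2 = 1, c3 = pars_mech$energetic$c3,
    split_x = pars_mech$energetic$split_x,
    muscle_mass_norm = pars_mech$energetic$muscle_mass_norm)
  rows <- lapply(met_trials, function(tr) {
    stopifnot(tr$trial_kind == "metabolic")
    win <- tr$metadata$avg_window
    if (is.null(win)) stop("metabolic trial lacks metadata$avg_window",
                           call. = FALSE)
    sim <- simulate_mtc(tr$input, pars_unit, options,
                        force_decline_ratio = tr$force_decline_ratio)
    sel <- sim$t >= win[1L] & sim$t <= win[2L]
    dur <- max(sim$t[sel]) - min(sim$t[sel])
    data.frame(
      a_low = trapz(sim$t[sel], sim$p_cb_low[sel]) / dur,
      b_high = trapz(sim$t[sel], sim$p_cb_high[sel]) / dur,
      g_bar = trapz(sim$t[sel], sim$gamma[sel]) / dur,
      power = tr$measured_mean_power,
      post = isTRUE(tr$blebbistatin),
      condition = tr$condition,
      id = tr$id %||% NA_character_)
  })
  tab <- do.call(rbind, rows)
  # c3 from post-blebbistatin trials: P = c3 * g_bar
  pp <- tab[tab$post, , drop = FALSE]
  c3 <- sum(pp$g_bar * pp$power) / sum(pp$g_bar^2)
  pre <- tab[!tab$post, , drop = FALSE]
  c1 <- NA_real_; c2 <- NA_real_; identifiable <- c(c1 = FALSE, c2 = FALSE)
  if (nrow(pre) >= 1L) {
    y <- pre$power - c3 * pre$g_bar
    X <- cbind(a_low = pre$a_low, b_high = pre$b_high)
    sv <- svd(X)
    keep <- sv$d > rank_tol * sv$d[1L]
    if (sum(keep) == 2L) {
      cc <- sv$v %*% ((t(sv$u) %*% y) / sv$d)
      c1 <- cc[1L]; c2 <- cc[2L]
      identifiable[] <- TRUE
    } else if (sum(keep) == 1L) {
      # only the dominant direction is identified; typically c2 when all
      # pre-blebbistatin trials lack long-bond-length unbinding mass
      warning("energetic design matrix is rank deficient: (c1, c2) not ",
              "jointly identifiable", call. = FALSE)
      cc <- sv$v[, 1L, drop = FALSE] %*% (t(sv$u[, 1L, drop = FALSE]) %*% y /
                                            sv$d[1L])
      c1 <- cc[1L]; c2 <- cc[2L]
      identifiable[] <- FALSE
    }
  }
  cb_pred <- if (is.na(c1)) rep(NA_real_, nrow(tab)) else
    c1 * tab$a_low + c2 * tab$b_high
  tab$pred <- c3 * tab$g_bar + ifelse(tab$post, 0, cb_pred)
  tab$rel_resid <- (tab$pred - tab$power) / tab$power
  rmse_pred_pct <- if (nrow(pre) > 0L && !any(is.na(tab$pred[!tab$post]))) {
    100 * sqrt(mean(tab$rel_resid[!tab$post]^2))
  } else NA_real_
  rmse_post_pct <- 100 * sqrt(mean(tab$rel_resid[tab$post]^2))
  en <- pars_mech$energetic
  en$c1 <- c1; en$c2 <- c2; en$c3 <- c3
  pars <- pars_mech
  pars$energetic <- en
  structure(list(energetic = en, pars = pars, trials = tab,
                 identifiable = identifiable,
                 rmse_pred_pct = rmse_pred_pct,
                 rmse_post_pct = rmse_post_pct),
            class = "energetic_fit")
}

#' Cross-validation matrix over bundles
#'
#' Entry (i, j) is the [evaluate_rmse()] cost of simulating bundle j's
#' trials with bundle i's fitted parameters. The diagonal reproduces each
#' bundle's own-fit objective exactly (same code path, same options).
#'
#' @param fits list of `dynamic_fit` objects (or `mtc_parameters`), one per
#'   bundle; `NULL` entries are allowed and yield `NA` rows.
#' @param trials_by_bundle list (same length) of trial lists.
#' @param options `sim_options`; defaults to the options stored in the
#'   first fit so the diagonal identity holds.
#' @param weighting passed to [rmse_rel()].
#' @return numeric matrix with `NA` for missing fits/trials.
#' @export
cross_validate <- function(fits, trials_by_bundle, options = NULL,
                           weighting = NULL) {
  nb <- length(fits)
  if (nb < 1L || length(trials_by_bundle) != nb)
    stop("need aligned fits and trials", call. = FALSE)
  first_fit <- Filter(function(f) inherits(f, "dynamic_fit"), fits)
  if (is.null(options))
    options <- if (length(first_fit)) first_fit[[1L]]$options else sim_options()
  if (is.null(weighting))
    weighting <- if (length(first_fit)) first_fit[[1L]]$weighting else "duration"
  m <- matrix(NA_real_, nb, nb,
              dimnames = list(params = paste0("A", seq_len(nb)),
                              data = paste0("A", seq_len(nb))))
  for (i in seq_len(nb)) {
    fi <- fits[[i]]
    if (is.null(fi)) next
    pi <- if (inherits(fi, "dynamic_fit")) fi$pars else fi
    for (j in seq_len(nb)) {
      if (is.null(trials_by_bundle[[j]])) next
      m[i, j] <- evaluate_rmse(pi, trials_by_bundle[[j]], options, weighting)
    }
  }
  m
}
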