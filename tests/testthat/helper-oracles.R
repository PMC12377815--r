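# Independent oracles: deliberately simple, brute-force implementations
# that share no code with the package's solution paths.

# Fixed-step RK4 integration of the distribution dynamics at u = 0 on a
# fixed grid (no advection), using the package's rate functions only
# through their public closed forms.
oracle_relax_u0 <- function(x, n0, drive_fun, pars, t_end, dt) {
  f <- attachment_rate(x, pars)
  g <- detachment_rate(x, pars)
  rhs <- function(tt, n) f * (drive_fun(tt) - n) - g * n
  n <- n0
  t <- 0
  nstep <- ceiling(t_end / dt)
  for (i in seq_len(nstep)) {
    k1 <- rhs(t, n)
    k2 <- rhs(t + dt / 2, n + dt * k1 / 2)
    k3 <- rhs(t + dt / 2, n + dt * k2 / 2)
    k4 <- rhs(t + dt, n + dt * k3)
    n <- n + dt * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    t <- t + dt
  }
  n
}

# First-order upwind finite-difference solver for the transport form of
# the distribution dynamics on a fixed (laboratory-frame) grid:
#   dn/dt = u dn/dx + f(x) (drive - n) - g(x) n,   u > 0 = shortening.
# Prescribed CE length trajectory lce_fun(t); gamma integrated alongside
# with the same closed-form rate. Returns CE force on out_times.
oracle_upwind_ce <- function(pars, lce_fun, dlce_fun, stim_fun, t_end,
                             out_times, nx = 1001, dt = 2e-5) {
  el <- pars$elastic
  g_par <- pars$grid
  x <- seq(g_par$x_lo, g_par$x_hi, length.out = nx)
  dx <- x[2] - x[1]
  fr <- attachment_rate(x, pars)
  gr <- detachment_rate(x, pars)
  m1_iso <- first_moment_norm(pars)
  c_u <- 2 * (el$l_ce_opt / pars$scale$s_opt) * pars$scale$h
  n <- numeric(nx)
  gam <- 0
  forces <- numeric(length(out_times))
  next_out <- 1L
  t <- 0
  nstep <- ceiling(t_end / dt)
  a <- pars$activation
  for (k in seq_len(nstep)) {
    if (next_out <= length(out_times) && t >= out_times[next_out] - dt / 2) {
      forces[next_out] <- el$f_max_ce * trapz(x, x * n) / m1_iso
      next_out <- next_out + 1L
    }
    st <- stim_fun(t)
    tau <- if (st > gam) a$tau_act else a$tau_deact
    gam <- gam + dt * (st - gam) / tau
    gam <- min(max(gam, 0), 1)
    q <- max(a$q_min, gam^a$n_coop / (gam^a$n_coop + a$kappa^a$n_coop))
    lce <- lce_fun(t)
    drive <- q * isometric_force_length(lce / el$l_ce_opt, el$ce_shape)
    u <- -dlce_fun(t) / c_u
    # upwind advection derivative for dn/dt = u * dn/dx + source
    if (u > 0) {
      adv <- u * c(diff(n) / dx, 0)           # forward difference
    } else {
      adv <- u * c(0, diff(n) / dx)           # backward difference
    }
    n <- n + dt * (adv + fr * (drive - n) - gr * n)
    t <- t + dt
  }
  while (next_out <= length(out_times)) {
    forces[next_out] <- el$f_max_ce * trapz(x, x * n) / m1_iso
    next_out <- next_out + 1L
  }
  forces
}

# Brute-force evaluation of the relative-RMSE cost: explicit loops over
# trials and samples, written directly from the cost definition.
oracle_rmse_rel <- function(model, measured, f_max, dt,
                            weighting = "duration") {
  N <- length(model)
  dt <- rep_len(dt, N)
  if (weighting == "duration") {
    num <- 0
    den <- 0
    for (i in seq_len(N)) {
      Ti <- dt[i] * length(model[[i]])
      acc <- 0
      for (k in seq_along(model[[i]])) {
        acc <- acc + (model[[i]][k] - measured[[i]][k])^2 * dt[i]
      }
      num <- num + acc
      den <- den + Ti
    }
    100 * sqrt(num / den) / f_max
  } else {
    acc <- 0
    for (i in seq_len(N)) {
      s <- 0
      for (k in seq_along(model[[i]])) {
        s <- s + (model[[i]][k] - measured[[i]][k])^2
      }
      acc <- acc + s / length(model[[i]])
    }
    100 * sqrt(acc / N) / f_max
  }
}

# Fixed-step RK4 simulation of the full MTC in which l_ce is NOT a
# quasi-state: the force balance is re-solved by root finding at every
# step. States: gamma and n on characteristics (node shift recomputed from
# the root-solved l_ce). Used to validate the quasi-state formulation.
oracle_rootsolve_mtc <- function(pars, input, t_end, dt) {
  el <- pars$elastic
  a <- pars$activation
  x0 <- xb_grid(pars)
  m1_iso <- first_moment_norm(pars)
  c_u <- 2 * (el$l_ce_opt / pars$scale$s_opt) * pars$scale$h
  lm_fun <- stats::splinefun(input$t, input$l_mtc, method = "monoH.FC")
  stim_fun <- function(tt) {
    any(tt >= input$pulse_times & tt < input$pulse_times + input$pulse_width)
  }
  st0 <- initialize_state(input$l_mtc[1], pars)
  gam <- 0
  lce_ref <- st0$l_ce
  n <- stats::approx(st0$distribution$x, st0$distribution$n, xout = x0,
                     yleft = 0, yright = 0)$y
  # root solve for l_ce given the current distribution (M1 depends on the
  # node shift, which itself depends on l_ce: affine relation)
  solve_lce <- function(lm, n, lce_ref, lce_guess) {
    m0 <- trapz(x0, n)
    m1_0 <- trapz(x0, x0 * n)
    bal <- function(lce) {
      m1 <- m1_0 + (lce - lce_ref) / c_u * m0
      see_force(lm - lce, pars) - el$f_max_ce * m1 / m1_iso -
        pee_force(lce, pars)
    }
    lo <- 0.2 * el$l_ce_opt
    hi <- lm - 1e-9
    stats::uniroot(bal, c(lo, hi), tol = 1e-14)$root
  }
  lce <- solve_lce(input$l_mtc[1], n, lce_ref, st0$l_ce)
  rhs <- function(tt, gam, n, lce_ref) {
    lm <- lm_fun(tt)
    lce <- solve_lce(lm, n, lce_ref, NULL)
    st <- as.numeric(stim_fun(tt))
    dgam <- (st - gam) / (if (st > gam) a$tau_act else a$tau_deact)
    q <- max(a$q_min,
             gam^a$n_coop / (gam^a$n_coop + a$kappa^a$n_coop))
    drive <- q * isometric_force_length(lce / el$l_ce_opt, el$ce_shape)
    xs <- x0 + (lce - lce_ref) / c_u
    dn <- attachment_rate(xs, pars) * (drive - n) -
      detachment_rate(xs, pars) * n
    list(dgam = dgam, dn = dn, lce = lce)
  }
  nstep <- ceiling(t_end / dt)
  t <- 0
  out <- data.frame(t = numeric(0), f_see = numeric(0), l_ce = numeric(0))
  for (k in seq_len(nstep)) {
    r1 <- rhs(t, gam, n, lce_ref)
    r2 <- rhs(t + dt / 2, gam + dt / 2 * r1$dgam, n + dt / 2 * r1$dn, lce_ref)
    r3 <- rhs(t + dt / 2, gam + dt / 2 * r2$dgam, n + dt / 2 * r2$dn, lce_ref)
    r4 <- rhs(t + dt, gam + dt * r3$dgam, n + dt * r3$dn, lce_ref)
    gam <- min(max(gam + dt / 6 * (r1$dgam + 2 * r2$dgam + 2 * r3$dgam +
                                     r4$dgam), 0), 1)
    n <- n + dt / 6 * (r1$dn + 2 * r2$dn + 2 * r3$dn + r4$dn)
    t <- t + dt
    lce <- solve_lce(lm_fun(t), n, lce_ref, NULL)
    # re-grid if the node drift grew beyond a quarter spacing
    shift <- (lce - lce_ref) / c_u
    dxg <- x0[2] - x0[1]
    if (abs(shift) > 0.25) {
      n <- stats::approx(x0 + shift, n, xout = x0, yleft = 0, yright = 0)$y
      lce_ref <- lce
    }
    out <- rbind(out, data.frame(t = t, f_see = see_force(lm_fun(t) - lce,
                                                          pars),
                                 l_ce = lce))
  }
  out
}
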