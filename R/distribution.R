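# The cross-bridge bond-length distribution: the model's main state.

#' Canonical bond-length grid
#'
#' @param pars `mtc_parameters`.
#' @return numeric vector of normalized bond lengths.
#' @export
xb_grid <- function(pars) {
  g <- pars$grid
  seq(g$x_lo, g$x_hi, length.out = g$n_nodes)
}

#' Construct a cross-bridge distribution
#'
#' @param x strictly increasing grid of normalized bond lengths.
#' @param n attached fractions aligned with `x`, each in \[0, 1\].
#' @return list of class `xb_distribution` with fields `x` and `n`.
#' @export
xb_distribution <- function(x, n) {
  stopifnot_finite(x, "x")
  stopifnot_finite(n, "n")
  if (length(x) != length(n)) stop("x and n must align", call. = FALSE)
  if (any(diff(x) <= 0)) stop("x must be strictly increasing", call. = FALSE)
  if (any(n < -1e-12 | n > 1 + 1e-12))
    stop("n must lie in [0, 1]", call. = FALSE)
  structure(list(x = x, n = pmin(pmax(n, 0), 1)), class = "xb_distribution")
}

#' Steady-state distribution at zero sliding velocity
#'
#' The analytic fixed point of the distribution dynamics for u = 0 and
#' constant drive: `n*(x) = drive * f(x) / (f(x) + g(x))`.
#'
#' @param pars `mtc_parameters`.
#' @param drive constant drive `q * F_isom` in \[0, 1\].
#' @param x grid (defaults to the canonical grid).
#' @return `xb_distribution`.
#' @export
xb_steady_state <- function(pars, drive = 1, x = xb_grid(pars)) {
  if (drive < 0 || drive > 1) stop("drive must lie in [0, 1]", call. = FALSE)
  f <- attachment_rate(x, pars)
  g <- detachment_rate(x, pars)
  n <- drive * f / (f + g)
  n[f + g == 0] <- 0
  xb_distribution(x, n)
}

#' Zeroth and first moments of a distribution
#'
#' Trapezoidal quadrature on the distribution's own grid.
#'
#' @param d `xb_distribution`.
#' @return named vector `c(m0, m1)`.
#' @export
distribution_moments <- function(d) {
  c(m0 = trapz(d$x, d$n), m1 = trapz(d$x, d$x * d$n))
}

#' First-moment normalization constant
#'
#' First moment of the isometric steady-state distribution at full drive
#' (u = 0, q = 1, optimal length), computed on the canonical grid with the
#' same quadrature used for force. CE force is normalized by this constant
#' so that the isometric steady state at full drive reproduces `f_max_ce`.
#'
#' @param pars `mtc_parameters`.
#' @return scalar.
#' @export
first_moment_norm <- function(pars) {
  d <- xb_steady_state(pars, drive = 1)
  unname(distribution_moments(d)["m1"])
}

#' Rate of change of the distribution along characteristics
#'
#' The transport equation for the attached fraction is solved along
#' characteristics that move with the filament sliding: grid nodes obey
#' `dx/dt = -u` (u > 0 shortening) while the attached fraction at each node
#' obeys `dn/dt = f(x) (drive - n) - g(x) n`. The attachment term is scaled
#' by the drive (active state times the isometric force-length value), so
#' the fixed point at u = 0 is `drive * f / (f + g)`.
#'
#' @param d `xb_distribution` (nodes at their current positions).
#' @param u normalized sliding velocity (1/s; positive while shortening).
#' @param drive scalar in \[0, 1\].
#' @param pars `mtc_parameters`.
#' @return list with `dn` (rate of n at each node, 1/s) and `dx` (common
#'   node velocity, = -u).
#' @export
distribution_rate <- function(d, u, drive, pars) {
  if (drive < -1e-12 || drive > 1 + 1e-12)
    stop("drive must lie in [0, 1]", call. = FALSE)
  f <- attachment_rate(d$x, pars)
  g <- detachment_rate(d$x, pars)
  list(dn = f * (drive - d$n) - g * d$n, dx = -u)
}

#' Contractile element force from the distribution
#'
#' Each attached cross-bridge exerts force proportional to its bond length,
#' so CE force is proportional to the first moment of the distribution,
#' normalized by the first moment of the isometric steady state at full
#' drive: `F_ce = f_max_ce * m1(n) / m1_iso`.
#'
#' @param d `xb_distribution`.
#' @param pars `mtc_parameters`.
#' @param m1_iso optional precomputed normalization constant.
#' @return force (N).
#' @export
ce_force <- function(d, pars, m1_iso = first_moment_norm(pars)) {
  if (!is.finite(m1_iso) || m1_iso <= 0)
    stop("first-moment normalization constant must be > 0", call. = FALSE)
  pars$elastic$f_max_ce * unname(distribution_moments(d)["m1"]) / m1_iso
}

#' Quasi-state rate of the contractile element length
#'
#' The force balance `F_see(l_mtc - l_ce) = F_ce + F_pee(l_ce)` is
#' maintained by treating `l_ce` as a quasi-state: differentiating the
#' balance in time and solving for `dl_ce/dt` gives
#'
#' `dl_ce/dt = (k_see dl_mtc/dt - A I_s + beta e) /
#'             (k_see + k_pee + A m0 / c_u + k_reg)`
#'
#' where `A = f_max_ce / m1_iso`, `I_s` is the first moment of the
#' reaction-term distribution rate, `m0` the zeroth moment (the
#' distribution's own stiffness contribution), `c_u = 2 n_sarc h`,
#' `e = F_see - F_ce - F_pee` the current balance residual, `beta` an
#' optional residual-feedback gain, and `k_reg` a small stiffness
#' regularization that keeps the expression defined when the SEE is at or
#' below slack with no attached cross-bridges (default
#' `1e-6 * f_max_ce / l_ce_opt`).
#'
#' @param state list with `gamma`, `l_ce` and `distribution`
#'   (an `xb_distribution` at current node positions).
#' @param l_mtc MTC length (m).
#' @param dl_mtc_dt MTC velocity (m/s).
#' @param pars `mtc_parameters`.
#' @param m1_iso optional precomputed normalization constant.
#' @param beta residual feedback gain (1/s), default 0.
#' @param k_reg stiffness regularization (N/m).
#' @return dl_ce/dt (m/s).
#' @export
lce_rate <- function(state, l_mtc, dl_mtc_dt, pars,
                     m1_iso = first_moment_norm(pars), beta = 0,
                     k_reg = 1e-6 * pars$elastic$f_max_ce / pars$elastic$l_ce_opt) {
  el <- pars$elastic
  d <- state$distribution
  l_ce <- state$l_ce
  l_see <- l_mtc - l_ce
  if (l_see < 0) stop("l_mtc shorter than l_ce", call. = FALSE)
  q <- active_state(state$gamma, pars)
  drive <- q * isometric_force_length(l_ce / el$l_ce_opt, el$ce_shape)
  rate <- distribution_rate(d, 0, drive, pars)
  i_s <- trapz(d$x, d$x * rate$dn)
  m <- distribution_moments(d)
  a_const <- el$f_max_ce / m1_iso
  c_u <- 2 * (el$l_ce_opt / pars$scale$s_opt) * pars$scale$h
  k_see <- see_stiffness(l_see, pars)
  k_pee <- pee_stiffness(l_ce, pars)
  resid <- see_force(l_see, pars) - ce_force(d, pars, m1_iso) -
    pee_force(l_ce, pars)
  (k_see * dl_mtc_dt - a_const * i_s + beta * resid) /
    (k_see + k_pee + a_const * m[["m0"]] / c_u + k_reg)
}

#' Steady-state CE force-velocity relation
#'
#' Integrates the characteristic ODE `dn/dx = -S(n, x) / u` (constant
#' sliding velocity, constant drive) across the grid to obtain the
#' steady-state distribution, and returns the corresponding normalized CE
#' force. Marching is from large x downward for shortening (u > 0) and from
#' small x upward for lengthening, following the characteristics.
#'
#' @param u normalized sliding velocities (1/s); positive = shortening.
#' @param pars `mtc_parameters`.
#' @param drive constant drive in \[0, 1\].
#' @param n_steps sub-steps per grid interval for the x-marching.
#' @return data.frame with `u` and normalized force `f_rel`.
#' @export
force_velocity <- function(u, pars, drive = 1, n_steps = 12L) {
  m1_iso <- first_moment_norm(pars)
  x <- xb_grid(pars)
  f <- attachment_rate(x, pars)
  g <- detachment_rate(x, pars)
  f_rel <- vapply(u, function(ui) {
    if (ui == 0) {
      n <- drive * f / (f + g)
      n[f + g == 0] <- 0
      return(trapz(x, x * n) / m1_iso)
    }
    # Steady state along x: 0 = S + u dn/dx, i.e. dn/dx = a(x) + b(x) n
    # with a = -f drive / u and b = (f + g) / u. Bonds flow in at n = 0
    # from the high-x end while shortening and from the low-x end while
    # lengthening. Marching in the flow direction, b * h < 0 always, so an
    # exponential update with midpoint-frozen coefficients is
    # unconditionally stable (and exact for frozen coefficients).
    n <- numeric(length(x))
    idx <- if (ui > 0) seq(length(x) - 1L, 1L) else seq(2L, length(x))
    for (i in idx) {
      j_prev <- if (ui > 0) i + 1L else i - 1L
      hstep <- (x[i] - x[j_prev]) / n_steps
      nv <- n[j_prev]
      xv <- x[j_prev]
      for (k in seq_len(n_steps)) {
        xm <- xv + hstep / 2
        fm <- attachment_rate(xm, pars)
        gm <- detachment_rate(xm, pars)
        a <- -fm * drive / ui
        b <- (fm + gm) / ui
        bh <- b * hstep
        if (abs(bh) < 1e-10) {
          nv <- nv + hstep * (a + b * nv)
        } else {
          nv <- (nv + a / b) * exp(bh) - a / b
        }
        xv <- xv + hstep
      }
      n[i] <- min(max(nv, 0), 1)
    }
    trapz(x, x * n) / m1_iso
  }, numeric(1))
  data.frame(u = u, f_rel = f_rel)
}
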