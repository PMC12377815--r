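# Constitutive relations of the elastic elements, the CE force-length
# relationship and the activation dynamics.

#' Series elastic element force
#'
#' Quadratic spring: zero below slack length, `c_see * (l - slack)^2` above.
#' The stiffness coefficient is defined through the strain at maximum
#' isometric CE force, so that `see_force(slack * (1 + strain_at_fmax))`
#' equals `f_max_ce` exactly.
#'
#' @param l_see SEE length (m), scalar or vector.
#' @param pars `mtc_parameters`.
#' @return force (N).
#' @export
see_force <- function(l_see, pars) {
  stopifnot_finite(l_see, "l_see")
  if (any(l_see < 0)) stop("l_see must be >= 0", call. = FALSE)
  el <- pars$elastic
  c_see <- el$f_max_ce / (el$see_strain_at_fmax * el$see_slack)^2
  ext <- pmax(l_see - el$see_slack, 0)
  c_see * ext^2
}

#' SEE tangent stiffness (N/m)
#' @keywords internal
see_stiffness <- function(l_see, pars) {
  el <- pars$elastic
  c_see <- el$f_max_ce / (el$see_strain_at_fmax * el$see_slack)^2
  2 * c_see * pmax(l_see - el$see_slack, 0)
}

#' Parallel elastic element force
#'
#' Same quadratic form as the SEE, with slack at `pee_slack_rel * l_ce_opt`
#' and stiffness set by the animal-specific shape parameter `pee_shape`
#' (the PEE strain, relative to its slack length, at which PEE force reaches
#' `f_max_ce`). With the defaults, passive force at optimum CE length is of
#' order 1% of maximum active force.
#'
#' @param l_ce CE length (m), scalar or vector.
#' @param pars `mtc_parameters`.
#' @return force (N).
#' @export
pee_force <- function(l_ce, pars) {
  stopifnot_finite(l_ce, "l_ce")
  if (any(l_ce < 0)) stop("l_ce must be >= 0", call. = FALSE)
  el <- pars$elastic
  pee_slack <- el$pee_slack_rel * el$l_ce_opt
  c_pee <- el$f_max_ce / (el$pee_shape * pee_slack)^2
  ext <- pmax(l_ce - pee_slack, 0)
  c_pee * ext^2
}

#' PEE tangent stiffness (N/m)
#' @keywords internal
pee_stiffness <- function(l_ce, pars) {
  el <- pars$elastic
  pee_slack <- el$pee_slack_rel * el$l_ce_opt
  c_pee <- el$f_max_ce / (el$pee_shape * pee_slack)^2
  2 * c_pee * pmax(l_ce - pee_slack, 0)
}

#' Normalized isometric CE force-length relationship
#'
#' Fourth-order polynomial in relative CE length, even in `(l_ce_rel - 1)`:
#' `F = (1 + (shape/2) * (l_ce_rel - 1)^2)^2` inside its roots and clamped
#' to zero outside. Equals 1 at optimum length; with the default shape -16
#' force vanishes at relative lengths `1 +/- sqrt(-2/shape) ~ 0.65 and 1.35`.
#'
#' @param l_ce_rel CE length normalized by optimum length (> 0).
#' @param ce_shape negative shape parameter (default -16).
#' @return normalized force in \[0, 1\].
#' @export
isometric_force_length <- function(l_ce_rel, ce_shape = -16) {
  stopifnot_finite(l_ce_rel, "l_ce_rel")
  if (any(l_ce_rel <= 0)) stop("l_ce_rel must be > 0", call. = FALSE)
  z <- (l_ce_rel - 1)^2
  f <- (1 + (ce_shape / 2) * z)^2
  f[z > -2 / ce_shape] <- 0
  pmin(f, 1)
}

#' Active state from free calcium
#'
#' Saturating sigmoid (Hill) relation
#' `q = gamma^n / (gamma^n + kappa^n)`, floored at `q_min`. By construction
#' `q(kappa) = 0.5` and `q(1) = 1 / (1 + kappa^n) < 1` is the saturation
#' value.
#'
#' @param gamma normalized free calcium concentration in \[0, 1\].
#' @param pars `mtc_parameters` (or an `activation_parameters` list).
#' @return active state q in \[q_min, 1\].
#' @export
active_state <- function(gamma, pars) {
  a <- if (inherits(pars, "mtc_parameters")) pars$activation else pars
  stopifnot_finite(gamma, "gamma")
  if (any(gamma < 0 | gamma > 1)) stop("gamma must lie in [0, 1]", call. = FALSE)
  gn <- gamma^a$n_coop
  pmax(a$q_min, gn / (gn + a$kappa^a$n_coop))
}

#' Rate of change of free calcium
#'
#' First-order relaxation of gamma toward the stimulation level, with time
#' constant `tau_act` while rising and `tau_deact` while falling.
#'
#' @param gamma current free calcium in \[0, 1\].
#' @param stim stimulation (0 or 1).
#' @param pars `mtc_parameters` (or an `activation_parameters` list).
#' @return d(gamma)/dt (1/s).
#' @export
calcium_rate <- function(gamma, stim, pars) {
  a <- if (inherits(pars, "mtc_parameters")) pars$activation else pars
  stopifnot_finite(c(gamma, stim), "gamma/stim")
  if (any(gamma < 0 | gamma > 1)) stop("gamma must lie in [0, 1]", call. = FALSE)
  tau <- ifelse(stim > gamma, a$tau_act, a$tau_deact)
  (stim - gamma) / tau
}

#' Normalized filament sliding velocity
#'
#' Converts a CE velocity into the velocity of the actin relative to the
#' myosin filament, expressed in normalized bond lengths per second. Each
#' half sarcomere contributes symmetrically, so sarcomere velocity is twice
#' the filament sliding velocity; the CE velocity is the sarcomere velocity
#' times the number of in-series sarcomeres `n_sarc = l_ce_opt / s_opt`.
#'
#' Sign convention (used everywhere in the package): `u > 0` denotes
#' shortening, under which the distribution advects toward smaller bond
#' lengths, i.e. characteristics obey `dx/dt = -u`.
#'
#' @param dl_ce_dt CE velocity (m/s; negative when shortening).
#' @param pars `mtc_parameters`.
#' @return u, normalized bond lengths per second.
#' @export
sliding_velocity <- function(dl_ce_dt, pars) {
  stopifnot_finite(dl_ce_dt, "dl_ce_dt")
  n_sarc <- pars$elastic$l_ce_opt / pars$scale$s_opt
  -dl_ce_dt / (2 * n_sarc * pars$scale$h)
}
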