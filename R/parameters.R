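# Parameter containers for one muscle-tendon complex ("bundle").
#
# Units are SI throughout the package: metres, newtons, seconds, W kg^-1.
# File I/O may declare mm / mN and is converted at the boundary (see
# read_parameters / write_parameters).

#' Elastic element and force-length parameters
#'
#' @param f_max_ce maximum isometric CE force (N).
#' @param l_ce_opt optimum CE length (m).
#' @param ce_shape dimensionless shape parameter of the normalized 4th-order
#'   CE force-length polynomial (negative; default -16).
#' @param see_slack SEE slack length (m).
#' @param see_strain_at_fmax SEE strain (relative to slack length) at which
#'   SEE force equals `f_max_ce`; default 0.04.
#' @param pee_slack_rel PEE slack length as a fraction of `l_ce_opt`;
#'   default 0.9.
#' @param pee_shape PEE strain (relative to PEE slack length) at which PEE
#'   force equals `f_max_ce`; the animal-specific PEE shape parameter.
#' @return list of class `elastic_parameters`.
#' @export
elastic_parameters <- function(f_max_ce = 16e-3, l_ce_opt = 6e-3,
                               ce_shape = -16, see_slack = 2.5e-3,
                               see_strain_at_fmax = 0.04,
                               pee_slack_rel = 0.9, pee_shape = 1.0) {
  stopifnot_finite(c(f_max_ce, l_ce_opt, ce_shape, see_slack,
                     see_strain_at_fmax, pee_slack_rel, pee_shape), "elastic")
  if (f_max_ce <= 0 || l_ce_opt <= 0 || see_slack <= 0)
    stop("forces and lengths must be > 0", call. = FALSE)
  if (see_strain_at_fmax <= 0 || see_strain_at_fmax >= 1)
    stop("see_strain_at_fmax must lie in (0, 1)", call. = FALSE)
  if (pee_slack_rel <= 0 || pee_slack_rel >= 1.5)
    stop("pee_slack_rel must lie in (0, 1.5)", call. = FALSE)
  if (ce_shape >= 0)
    stop("ce_shape must be negative", call. = FALSE)
  if (pee_shape <= 0)
    stop("pee_shape must be > 0", call. = FALSE)
  structure(list(
    f_max_ce = f_max_ce, l_ce_opt = l_ce_opt, ce_shape = ce_shape,
    see_slack = see_slack, see_strain_at_fmax = see_strain_at_fmax,
    pee_slack_rel = pee_slack_rel, pee_shape = pee_shape
  ), class = "elastic_parameters")
}

#' Activation (calcium) dynamics parameters
#'
#' @param tau_act activation time constant (s).
#' @param tau_deact deactivation time constant (s).
#' @param kappa free-calcium level at which half of the cross-bridges
#'   participate (dimensionless, in (0, 1)).
#' @param n_coop cooperativity coefficient of calcium binding (>= 1).
#' @param q_min floor on the active state (default 1e-6).
#' @return list of class `activation_parameters`.
#' @export
activation_parameters <- function(tau_act = 0.030, tau_deact = 0.070,
                                  kappa = 0.35, n_coop = 2, q_min = 1e-6) {
  stopifnot_finite(c(tau_act, tau_deact, kappa, n_coop, q_min), "activation")
  if (tau_act <= 0 || tau_deact <= 0)
    stop("time constants must be > 0", call. = FALSE)
  if (kappa <= 0 || kappa >= 1)
    stop("kappa must lie in (0, 1)", call. = FALSE)
  if (n_coop < 1) stop("n_coop must be >= 1", call. = FALSE)
  if (q_min <= 0 || q_min > 1e-2)
    stop("q_min must be a small positive floor", call. = FALSE)
  structure(list(
    tau_act = tau_act, tau_deact = tau_deact, kappa = kappa,
    n_coop = n_coop, q_min = q_min
  ), class = "activation_parameters")
}

#' Cross-bridge attachment/detachment rate parameters
#'
#' Rates apply to the bond length normalized by the maximum attachment bond
#' length, so all rate parameters have units Hz.
#'
#' @param f1 attachment rate slope on (0, 1) (Hz).
#' @param g1 detachment rate slope on (0, 1) (Hz); fixed at 100 Hz by
#'   convention because isometric energy-rate data to identify it are absent.
#' @param g2 detachment rate for negative bond lengths (Hz).
#' @param g3 extra detachment rate beyond the attachment window (Hz), which
#'   vertically shifts the detachment line for x > 1 and caps eccentric force.
#' @param smooth_width width of the Gaussian smoothing region at the kinks
#'   x = 0 and x = 1 (normalized bond length; default 0.2).
#' @return list of class `rate_parameters`.
#' @export
rate_parameters <- function(f1 = 700, g1 = 100, g2 = 1.2e4, g3 = 500,
                            smooth_width = 0.2) {
  stopifnot_finite(c(f1, g1, g2, g3, smooth_width), "rates")
  if (any(c(f1, g1, g2, g3) < 0)) stop("rates must be >= 0", call. = FALSE)
  if (smooth_width <= 0) stop("smooth_width must be > 0", call. = FALSE)
  structure(list(
    f1 = f1, g1 = g1, g2 = g2, g3 = g3, smooth_width = smooth_width
  ), class = "rate_parameters")
}

#' Sarcomere scaling parameters
#'
#' @param h maximum attachment bond length (m); default 1e-8.
#' @param s_opt optimum sarcomere length (m); default 2.4e-6 (mouse).
#' @return list of class `scale_parameters`.
#' @export
scale_parameters <- function(h = 1e-8, s_opt = 2.4e-6) {
  stopifnot_finite(c(h, s_opt), "scale")
  if (h <= 0 || s_opt <= 0) stop("h and s_opt must be > 0", call. = FALSE)
  structure(list(h = h, s_opt = s_opt), class = "scale_parameters")
}

#' Metabolic energetics parameters
#'
#' @param c1 cost weight of cross-bridge unbinding below `split_x`
#'   (J kg^-1 m^-1).
#' @param c2 cost weight of unbinding at or above `split_x` (J kg^-1 m^-1);
#'   detachment at long bond lengths during lengthening is partly mechanical
#'   ("free"), hence the separate, typically smaller weight.
#' @param c3 calcium-pumping cost coefficient (W kg^-1 at gamma = 1).
#' @param split_x normalized bond length separating the two unbinding
#'   integrals (default 0.8).
#' @param muscle_mass_norm reference muscle mass (kg) used to convert per-kg
#'   powers to absolute energy in efficiency bookkeeping; default 6e-7 kg,
#'   the approximate mass of a ~70-fibre soleus bundle.
#' @return list of class `energetic_parameters`.
#' @export
energetic_parameters <- function(c1 = 0.16, c2 = 0.06, c3 = 100,
                                 split_x = 0.8, muscle_mass_norm = 6e-7) {
  stopifnot_finite(c(c1, c2, c3, split_x, muscle_mass_norm), "energetics")
  if (c1 < 0 || c2 < 0 || c3 < 0)
    stop("c1, c2, c3 must be >= 0", call. = FALSE)
  if (split_x <= 0) stop("split_x must be > 0", call. = FALSE)
  if (muscle_mass_norm <= 0) stop("muscle_mass_norm must be > 0", call. = FALSE)
  structure(list(
    c1 = c1, c2 = c2, c3 = c3, split_x = split_x,
    muscle_mass_norm = muscle_mass_norm
  ), class = "energetic_parameters")
}

#' Bond-length grid specification
#'
#' Canonical grid of normalized bond lengths carrying the attached-fraction
#' distribution. The default extent \[-2, 3\] with 201 nodes keeps boundary
#' mass negligible in all protocol trials.
#'
#' @param x_lo,x_hi grid extent (must satisfy `x_lo < 0 < 1 < x_hi`).
#' @param n_nodes number of grid nodes.
#' @return list of class `grid_parameters`.
#' @export
grid_parameters <- function(x_lo = -2, x_hi = 3, n_nodes = 201L) {
  if (!(x_lo < 0 && 1 < x_hi)) stop("need x_lo < 0 < 1 < x_hi", call. = FALSE)
  if (n_nodes < 21L) stop("n_nodes too small", call. = FALSE)
  structure(list(x_lo = x_lo, x_hi = x_hi, n_nodes = as.integer(n_nodes)),
            class = "grid_parameters")
}

#' Full parameter set for one muscle-tendon complex
#'
#' Bundles the elastic, activation, rate, scale, energetic and grid
#' parameter groups for one animal/fibre bundle.
#'
#' @param elastic [elastic_parameters()].
#' @param activation [activation_parameters()].
#' @param rates [rate_parameters()].
#' @param scale [scale_parameters()].
#' @param energetic [energetic_parameters()].
#' @param grid [grid_parameters()].
#' @return list of class `mtc_parameters`.
#' @export
mtc_parameters <- function(elastic = elastic_parameters(),
                           activation = activation_parameters(),
                           rates = rate_parameters(),
                           scale = scale_parameters(),
                           energetic = energetic_parameters(),
                           grid = grid_parameters()) {
  stopifnot(inherits(elastic, "elastic_parameters"),
            inherits(activation, "activation_parameters"),
            inherits(rates, "rate_parameters"),
            inherits(scale, "scale_parameters"),
            inherits(energetic, "energetic_parameters"),
            inherits(grid, "grid_parameters"))
  n_sarc <- elastic$l_ce_opt / scale$s_opt
  if (n_sarc <= 1) stop("l_ce_opt / s_opt must exceed 1", call. = FALSE)
  structure(list(elastic = elastic, activation = activation, rates = rates,
                 scale = scale, energetic = energetic, grid = grid),
            class = "mtc_parameters")
}

#' Default parameter set
#'
#' A representative mouse soleus fibre bundle: maximum CE force 16 mN,
#' optimum CE length 6 mm, tendon slack 2.5 mm, mid-range rate and
#' activation constants.
#'
#' @return `mtc_parameters` object.
#' @export
default_parameters <- function() mtc_parameters()

#' Derived constants of a parameter set
#'
#' Computes the quantities implied by the primary parameters: quadratic
#' spring stiffness coefficients, the number of in-series sarcomeres, the
#' CE-velocity-to-filament-velocity conversion, and the first-moment force
#' normalization constant.
#'
#' @param pars `mtc_parameters`.
#' @return named list: `c_see`, `c_pee` (N m^-2), `pee_slack` (m), `n_sarc`,
#'   `c_u` (m per normalized bond length), `m1_iso`.
#' @export
derived_constants <- function(pars) {
  el <- pars$elastic
  c_see <- el$f_max_ce / (el$see_strain_at_fmax * el$see_slack)^2
  pee_slack <- el$pee_slack_rel * el$l_ce_opt
  c_pee <- el$f_max_ce / (el$pee_shape * pee_slack)^2
  n_sarc <- el$l_ce_opt / pars$scale$s_opt
  c_u <- 2 * n_sarc * pars$scale$h
  list(c_see = c_see, c_pee = c_pee, pee_slack = pee_slack,
       n_sarc = n_sarc, c_u = c_u, m1_iso = first_moment_norm(pars))
}

#' @export
print.mtc_parameters <- function(x, ...) {
  el <- x$elastic
  cat("Huxley MTC parameter set\n")
  cat(sprintf("  F_max %.3g mN | l_ce_opt %.3g mm | SEE slack %.3g mm\n",
              1e3 * el$f_max_ce, 1e3 * el$l_ce_opt, 1e3 * el$see_slack))
  cat(sprintf("  rates: f1 %.3g, g1 %.3g, g2 %.3g, g3 %.3g Hz\n",
              x$rates$f1, x$rates$g1, x$rates$g2, x$rates$g3))
  cat(sprintf("  activation: tau_act %.3g s, tau_deact %.3g s, kappa %.3g, n %.3g\n",
              x$activation$tau_act, x$activation$tau_deact,
              x$activation$kappa, x$activation$n_coop))
  cat(sprintf("  energetics: c1 %.3g, c2 %.3g J kg-1 m-1, c3 %.3g W kg-1\n",
              x$energetic$c1, x$energetic$c2, x$energetic$c3))
  invisible(x)
}

#' Write a parameter set to JSON
#'
#' Parameters are stored with an explicit units block so files are
#' self-describing. Lengths are written in metres.
#'
#' @param pars `mtc_parameters`.
#' @param path output file path.
#' @export
write_parameters <- function(pars, path) {
  stopifnot(inherits(pars, "mtc_parameters"))
  obj <- lapply(unclass(pars), unclass)
  obj$units <- list(length = "m", force = "N", time = "s",
                    c1 = "J kg-1 m-1", c2 = "J kg-1 m-1", c3 = "W kg-1")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a parameter set from JSON
#'
#' @param path file written by [write_parameters()].
#' @return `mtc_parameters`.
#' @export
read_parameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mtc_parameters(
    elastic = do.call(elastic_parameters, obj$elastic),
    activation = do.call(activation_parameters, obj$activation),
    rates = do.call(rate_parameters, obj$rates),
    scale = do.call(scale_parameters, obj$scale),
    energetic = do.call(energetic_parameters, obj$energetic),
    grid = do.call(grid_parameters, obj$grid)
  )
}
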