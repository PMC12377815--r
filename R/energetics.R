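# Metabolic power: cross-bridge unbinding cost plus calcium-pumping cost.

#' Split unbinding rate-moments of a distribution
#'
#' Computes `int g(x) n(x) dx` below and at/above the split bond length on
#' the distribution's grid (trapezoidal rule with an interpolated node
#' inserted exactly at the split). The rate of cross-bridge unbinding is
#' the quantity metabolic power is proportional to; the split separates
#' ordinary cycling (weight c1) from detachment at long bond lengths during
#' lengthening, which is partly mechanical rather than chemical (weight c2).
#'
#' @param d `xb_distribution`.
#' @param pars `mtc_parameters`.
#' @param split_x split point (defaults to the parameter set's value).
#' @return named vector `c(low, high)` (1/s), both non-negative.
#' @export
unbinding_integrals <- function(d, pars,
                                split_x = pars$energetic$split_x) {
  gn <- detachment_rate(d$x, pars) * d$n
  x <- d$x
  if (split_x <= x[1L]) {
    return(c(low = 0, high = trapz(x, gn)))
  }
  if (split_x >= x[length(x)]) {
    return(c(low = trapz(x, gn), high = 0))
  }
  i <- findInterval(split_x, x)
  # value at the split by linear interpolation of the integrand
  w <- (split_x - x[i]) / (x[i + 1L] - x[i])
  gn_s <- (1 - w) * gn[i] + w * gn[i + 1L]
  low <- trapz(c(x[seq_len(i)], split_x), c(gn[seq_len(i)], gn_s))
  high <- trapz(c(split_x, x[seq(i + 1L, length(x))]),
                c(gn_s, gn[seq(i + 1L, length(x))]))
  c(low = max(low, 0), high = max(high, 0))
}

#' Dimensional scale of the cross-bridge power terms
#'
#' Centralizes the conversion from the grid rate-moment (1/s) to W kg^-1:
#' `scale = h * n_sarc / m1_iso`. One unbinding event per site corresponds
#' to one maximum bond length `h` of filament travel; summed over the
#' `n_sarc` in-series sarcomeres this is an equivalent CE displacement, so
#' multiplying a coefficient in J kg^-1 m^-1 by `scale * integral` yields
#' W kg^-1. The `1/m1_iso` factor mirrors the cross-bridge stiffness
#' normalization used in the force equation. Any alternative reading of the
#' prefactor changes only this function.
#'
#' @param pars `mtc_parameters`.
#' @param m1_iso optional precomputed normalization constant.
#' @return scalar (m).
#' @export
cb_power_scale <- function(pars, m1_iso = first_moment_norm(pars)) {
  n_sarc <- pars$elastic$l_ce_opt / pars$scale$s_opt
  pars$scale$h * n_sarc / m1_iso
}

#' Calcium-pumping (activation) metabolic power
#'
#' Pump rate, and hence power, is proportional to the free calcium
#' concentration: `P_act = c3 * gamma`.
#'
#' @param gamma free calcium in \[0, 1\].
#' @param pars `mtc_parameters` (or an `energetic_parameters` list).
#' @return power (W kg^-1).
#' @export
activation_power <- function(gamma, pars) {
  e <- if (inherits(pars, "mtc_parameters")) pars$energetic else pars
  stopifnot_finite(gamma, "gamma")
  if (any(gamma < 0 | gamma > 1)) stop("gamma must lie in [0, 1]", call. = FALSE)
  e$c3 * gamma
}

#' Total metabolic power breakdown
#'
#' Sum of the two weighted unbinding terms and the calcium-pumping term.
#' The cross-bridge terms are multiplied by the within-trial force-decline
#' ratio (average force over the whole trial relative to the first
#' contraction); in blebbistatin mode cross-bridge cycling is disabled and
#' the unbinding integrals are zeroed, leaving `P_total = c3 * gamma`.
#'
#' @param d `xb_distribution`.
#' @param gamma free calcium in \[0, 1\].
#' @param pars `mtc_parameters`.
#' @param blebbistatin logical; zero the cross-bridge terms.
#' @param force_decline_ratio scalar in (0, 1\].
#' @param m1_iso optional precomputed normalization constant.
#' @return named list `p_cb_low`, `p_cb_high`, `p_act`, `p_total`
#'   (all W kg^-1, non-negative; `p_total` is their sum).
#' @export
total_power <- function(d, gamma, pars, blebbistatin = FALSE,
                        force_decline_ratio = 1,
                        m1_iso = first_moment_norm(pars)) {
  if (!is.finite(force_decline_ratio) || force_decline_ratio <= 0 ||
      force_decline_ratio > 1)
    stop("force_decline_ratio must lie in (0, 1]", call. = FALSE)
  e <- pars$energetic
  if (blebbistatin) {
    p_low <- 0
    p_high <- 0
  } else {
    ints <- unbinding_integrals(d, pars)
    sc <- cb_power_scale(pars, m1_iso) * force_decline_ratio
    p_low <- e$c1 * sc * ints[["low"]]
    p_high <- e$c2 * sc * ints[["high"]]
  }
  p_act <- activation_power(gamma, pars)
  list(p_cb_low = p_low, p_cb_high = p_high, p_act = p_act,
       p_total = p_low + p_high + p_act)
}
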