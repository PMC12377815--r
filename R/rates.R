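# Cross-bridge attachment and detachment rate functions.
#
# The underlying piecewise-linear rates (attachment f1*x on the unit
# interval, detachment g2 below zero / g1*x on the unit interval /
# g1*x + g3 beyond it) are smoothed at the kinks x = 0 and x = 1 by
# convolution with a Gaussian kernel whose +/-2 sigma support equals the
# `smooth_width` window (sigma = smooth_width / 4). The convolution has a
# closed form in the normal density/CDF, is continuously differentiable,
# non-negative, and agrees with the piecewise-linear branches to machine
# precision outside the smoothing windows.

#' Cross-bridge attachment rate f(x)
#'
#' @param x normalized bond length, scalar or vector.
#' @param pars `mtc_parameters` (or a `rate_parameters` list).
#' @return attachment rate (Hz), non-negative.
#' @export
attachment_rate <- function(x, pars) {
  r <- if (inherits(pars, "mtc_parameters")) pars$rates else pars
  sigma <- r$smooth_width / 4
  a <- (0 - x) / sigma
  b <- (1 - x) / sigma
  # the exact convolution is non-negative; clamp floating-point residue
  pmax(r$f1 * (x * (stats::pnorm(b) - stats::pnorm(a)) +
                 sigma * (stats::dnorm(a) - stats::dnorm(b))), 0)
}

#' Cross-bridge detachment rate g(x)
#'
#' Constant `g2` below x = 0, slope `g1 * x` on the unit interval, and
#' `g1 * x + g3` beyond x = 1 (the `g3` offset vertically shifts the
#' detachment line and limits eccentric force). Strictly positive outside
#' the attachment window so the distribution decays there.
#'
#' @param x normalized bond length, scalar or vector.
#' @param pars `mtc_parameters` (or a `rate_parameters` list).
#' @return detachment rate (Hz), non-negative.
#' @export
detachment_rate <- function(x, pars) {
  r <- if (inherits(pars, "mtc_parameters")) pars$rates else pars
  sigma <- r$smooth_width / 4
  a <- (0 - x) / sigma
  b <- (1 - x) / sigma
  mid <- x * (stats::pnorm(b) - stats::pnorm(a)) +
    sigma * (stats::dnorm(a) - stats::dnorm(b))
  high <- x * (1 - stats::pnorm(b)) + sigma * stats::dnorm(b)
  pmax(r$g2 * stats::pnorm(a) + r$g1 * (mid + high) +
         r$g3 * (1 - stats::pnorm(b)), 0)
}

#' Analytic derivatives of the smoothed rate functions
#' @keywords internal
attachment_rate_deriv <- function(x, pars) {
  r <- if (inherits(pars, "mtc_parameters")) pars$rates else pars
  sigma <- r$smooth_width / 4
  a <- (0 - x) / sigma
  b <- (1 - x) / sigma
  r$f1 * (stats::pnorm(b) - stats::pnorm(a) - stats::dnorm(b) / sigma)
}

#' @rdname attachment_rate_deriv
#' @keywords internal
detachment_rate_deriv <- function(x, pars) {
  r <- if (inherits(pars, "mtc_parameters")) pars$rates else pars
  sigma <- r$smooth_width / 4
  a <- (0 - x) / sigma
  b <- (1 - x) / sigma
  -r$g2 * stats::dnorm(a) / sigma + r$g1 * (1 - stats::pnorm(a)) +
    r$g3 * stats::dnorm(b) / sigma
}

#' Lookup-table representation of the rate functions
#'
#' Pre-evaluates f(x), g(x) and their analytic derivatives on a fine
#' uniform grid for the compiled integrator, which interpolates with a
#' cubic Hermite (error well below the integrator tolerance). The table
#' spans the canonical distribution grid plus the maximum re-grid drift
#' margin.
#'
#' @param pars `mtc_parameters`.
#' @param margin extra extent beyond the canonical grid (normalized x).
#' @param dx table spacing (normalized x).
#' @return list with `x0`, `dx`, `f`, `g`, `fp`, `gp`.
#' @keywords internal
rate_table <- function(pars, margin = 0.6, dx = 0.002) {
  g <- pars$grid
  x <- seq(g$x_lo - margin, g$x_hi + margin + dx, by = dx)
  list(x0 = x[1L], dx = dx, f = attachment_rate(x, pars),
       g = detachment_rate(x, pars),
       fp = attachment_rate_deriv(x, pars),
       gp = detachment_rate_deriv(x, pars), x = x)
}
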