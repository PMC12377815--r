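# Small numerical helpers shared across the package.

#' Trapezoidal quadrature on an ordered grid
#'
#' @param x ordered abscissa vector.
#' @param y values aligned with `x`.
#' @return scalar integral approximation.
#' @keywords internal
trapz <- function(x, y) {
  nx <- length(x)
  if (nx < 2L) return(0)
  sum((x[-1L] - x[-nx]) * (y[-1L] + y[-nx])) / 2
}

#' Fritsch-Carlson monotone cubic Hermite slopes
#'
#' Returns knot slopes for a shape-preserving cubic Hermite interpolant,
#' matching `stats::splinefun(method = "monoH.FC")` behaviour closely enough
#' for trajectory interpolation. Used to hand knot slopes to the compiled
#' integrator.
#'
#' @param x strictly increasing knots.
#' @param y values at knots.
#' @return slope vector of `length(x)`.
#' @keywords internal
monotone_slopes <- function(x, y) {
  n <- length(x)
  if (n == 1L) return(0)
  h <- diff(x)
  delta <- diff(y) / h
  d <- numeric(n)
  if (n == 2L) {
    d[] <- delta
    return(d)
  }
  d[1L] <- delta[1L]
  d[n] <- delta[n - 1L]
  for (i in 2:(n - 1L)) {
    if (delta[i - 1L] * delta[i] <= 0) {
      d[i] <- 0
    } else {
      w1 <- 2 * h[i] + h[i - 1L]
      w2 <- h[i] + 2 * h[i - 1L]
      d[i] <- (w1 + w2) / (w1 / delta[i - 1L] + w2 / delta[i])
    }
  }
  # Fritsch-Carlson limiter
  for (i in seq_len(n - 1L)) {
    if (delta[i] == 0) {
      d[i] <- 0
      d[i + 1L] <- 0
    } else {
      a <- d[i] / delta[i]
      b <- d[i + 1L] / delta[i]
      s <- a * a + b * b
      if (s > 9) {
        tau <- 3 / sqrt(s)
        d[i] <- tau * a * delta[i]
        d[i + 1L] <- tau * b * delta[i]
      }
    }
  }
  d
}

#' Evaluate a cubic Hermite interpolant and its derivative
#' @keywords internal
hermite_eval <- function(t, x, y, d, deriv = 0L) {
  i <- findInterval(t, x, rightmost.closed = TRUE, all.inside = TRUE)
  h <- x[i + 1L] - x[i]
  th <- (t - x[i]) / h
  if (deriv == 0L) {
    h00 <- (1 + 2 * th) * (1 - th)^2
    h10 <- th * (1 - th)^2
    h01 <- th^2 * (3 - 2 * th)
    h11 <- th^2 * (th - 1)
    h00 * y[i] + h10 * h * d[i] + h01 * y[i + 1L] + h11 * h * d[i + 1L]
  } else {
    dh00 <- 6 * th * (th - 1) / h
    dh10 <- (3 * th^2 - 4 * th + 1)
    dh01 <- -6 * th * (th - 1) / h
    dh11 <- (3 * th^2 - 2 * th)
    dh00 * y[i] + dh10 * d[i] + dh01 * y[i + 1L] + dh11 * d[i + 1L]
  }
}

stopifnot_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    stop(sprintf("'%s' must be finite", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
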