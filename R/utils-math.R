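# Numerical utilities shared across modules.

#' Scaled complementary error function
#'
#' `erfcx(z) = exp(z^2) * erfc(z)`, evaluated without overflow via the
#' normal log-tail: `erfc(z) = 2 * pnorm(-z*sqrt(2))`, so
#' `erfcx(z) = exp(z^2 + log(2) + log(pnorm(-z*sqrt(2))))`.  For large
#' negative z the identity `erfcx(z) = 2*exp(z^2) - erfcx(-z)` applies;
#' callers that need boundedness there must combine it with a decaying
#' factor (see [transition_pdf()]).
#'
#' @param z Numeric vector.
#' @return `exp(z^2) * erfc(z)`.
#' @keywords internal
erfcx <- function(z) {
  out <- numeric(length(z))
  pos <- z >= 0
  if (any(pos)) {
    zp <- z[pos]
    # the z^2 + log-tail route loses ~eps * z^2 of absolute precision in
    # the exponent; past z ~ 1e4 the asymptotic series is far better
    big <- zp > 1e4
    o <- numeric(length(zp))
    if (any(big)) {
      zb <- zp[big]
      o[big] <- (1 - 1 / (2 * zb^2) + 3 / (4 * zb^4)) / (zb * sqrt(pi))
    }
    if (any(!big)) {
      zs <- zp[!big]
      o[!big] <- exp(zs^2 + log(2) +
                       stats::pnorm(zs * sqrt(2), lower.tail = FALSE,
                                    log.p = TRUE))
    }
    out[pos] <- o
  }
  if (any(!pos)) {
    zn <- z[!pos]
    out[!pos] <- 2 * exp(zn^2) - erfcx(-zn)
  }
  out
}

#' Trapezoidal integral on a grid
#' @param x Abscissae (increasing).
#' @param y Ordinates.
#' @return The trapezoid-rule integral.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Central moments of a gridded density by trapezoid rule
#' @param x Grid.
#' @param dens Density values.
#' @return List with `mass`, `mean`, `variance`, `excess_kurtosis`.
#' @keywords internal
grid_moments <- function(x, dens) {
  mass <- trapz(x, dens)
  mu <- trapz(x, x * dens) / mass
  v <- trapz(x, (x - mu)^2 * dens) / mass
  m4 <- trapz(x, (x - mu)^4 * dens) / mass
  list(mass = mass, mean = mu, variance = v,
       excess_kurtosis = m4 / v^2 - 3)
}
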