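#' Gridded displacement probability density
#'
#' Light container pairing a displacement grid (um) with density values
#' (per um), the observation time, and the regime the curve belongs to.
#' Construction validates nonnegativity and unit mass (trapezoid rule,
#' tolerance 1e-6) unless `normalized = FALSE`.
#'
#' @param grid Displacement abscissae in um, strictly increasing,
#'   symmetric about 0 for 1-D densities.
#' @param density Density values, per um, same length as `grid`.
#' @param time Observation time in seconds.
#' @param regime_label One of `"gas"`, `"transition"`, `"mixture"`.
#' @param normalized Logical; when `TRUE` (default) unit mass is enforced.
#' @return An object of class `displacement_pdf`.
#' @export
displacement_pdf <- function(grid, density, time,
                             regime_label = c("gas", "transition",
                                              "mixture"),
                             normalized = TRUE) {
  regime_label <- match.arg(regime_label)
  stopifnot(is.numeric(grid), is.numeric(density),
            length(grid) == length(density), length(grid) >= 3L,
            all(is.finite(grid)), all(is.finite(density)),
            is.numeric(time), length(time) == 1L, time >= 0)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (any(density < 0)) stop("density must be nonnegative")
  if (normalized) {
    mass <- trapz(grid, density)
    if (abs(mass - 1) > 1e-6)
      stop(sprintf("density mass %.8f deviates from 1 by more than 1e-6",
                   mass))
  }
  structure(list(grid = grid, density = density, time = time,
                 regime_label = regime_label),
            class = "displacement_pdf")
}

#' @export
print.displacement_pdf <- function(x, ...) {
  m <- grid_moments(x$grid, x$density)
  cat(sprintf(
    "<displacement_pdf> t = %.4g s, regime = %s, %d grid points\n",
    x$time, x$regime_label, length(x$grid)))
  cat(sprintf("  mass %.6f, variance %.4g um^2, excess kurtosis %.4g\n",
              m$mass, m$variance, m$excess_kurtosis))
  invisible(x)
}

#' Moments of a displacement density
#'
#' Trapezoid-rule mass, mean, variance and excess kurtosis of a
#' [displacement_pdf()].
#'
#' @param pdf A `displacement_pdf`.
#' @return List with `mass`, `mean`, `variance`, `excess_kurtosis`.
#' @export
pdf_moments <- function(pdf) {
  stopifnot(inherits(pdf, "displacement_pdf"))
  grid_moments(pdf$grid, pdf$density)
}

#' Propagator of overdamped diffusion with dry-friction drift
#'
#' Transition density of the nondimensionalised process
#' `dX = -sgn(X) dtau + sqrt(2) dW` (drift magnitude and microscopic
#' diffusivity both scaled to 1; length unit D_m/mu, time unit D_m/mu^2
#' with mu the drift magnitude and D_m the microscopic diffusivity):
#'
#' `P(r, tau | r0) = exp(-(r-r0)^2/(4 tau) - (|r|-|r0|)/2 - tau/4) /
#'   sqrt(4 pi tau) + (1/4) exp(-|r|) erfc((|r|+|r0|-tau)/sqrt(4 tau))`
#'
#' It is nonnegative, integrates to 1, and converges for `tau -> Inf` to
#' the stationary Boltzmann--Gibbs law of the linear potential, the unit
#' Laplace density `(1/2) exp(-|r|)`.
#'
#' @param r Evaluation points (dimensionless, vectorised).
#' @param tau Dimensionless time, positive scalar.
#' @param r0 Dimensionless starting point (delta initial condition).
#' @return Transition density values (dimensionless).
#' @export
dry_friction_propagator <- function(r, tau, r0 = 0) {
  stopifnot(is.numeric(r), is.numeric(tau), length(tau) == 1L,
            is.numeric(r0), length(r0) == 1L)
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  gauss <- exp(-(r - r0)^2 / (4 * tau) - (abs(r) - abs(r0)) / 2 - tau / 4) /
    sqrt(4 * pi * tau)
  tail <- 0.25 * exp(-abs(r)) *
    2 * stats::pnorm((abs(r) + abs(r0) - tau) / sqrt(2 * tau),
                     lower.tail = FALSE)
  gauss + tail
}

#' Laplace displacement density of the gas-like phase
#'
#' The stationary displacement law of the dry-friction process at time t
#' is the Laplace (double-exponential) density
#' `p(x) = exp(-|x|/lambda) / (2 lambda)` with scale
#' `lambda = sqrt(Deff * t)`, so the variance `2 lambda^2 = 2 Deff t` grows
#' linearly in time: Brownian yet non-Gaussian.  With `rescale = TRUE`
#' (the observation convention) the scale uses the mixture average `Davg`
#' so the variance matches the measured MSD `2 Davg t`; otherwise the
#' gas-like-phase diffusivity `DeffG` is used.
#'
#' @param x Displacement in um (vectorised).
#' @param t Time in seconds, positive scalar.
#' @param phase A [phase_params()] object.
#' @param rescale Logical; `TRUE` (default) uses `lambda = sqrt(Davg*t)`,
#'   `FALSE` uses `lambda = sqrt(DeffG*t)`.
#' @return Density values, per um.
#' @export
laplace_pdf <- function(x, t, phase, rescale = TRUE) {
  stopifnot(inherits(phase, "phase_params"), is.numeric(x),
            is.numeric(t), length(t) == 1L)
  if (!is.finite(t) || t <= 0) stop("t must be positive")
  lambda <- sqrt((if (isTRUE(rescale)) phase$Davg else phase$DeffG) * t)
  exp(-abs(x) / lambda) / (2 * lambda)
}

#' Laplace-to-Gaussian transition density
#'
#' Exact density of the Laplace initial condition (scale `lambda0`, the
#' gas-like law frozen at the critical time) propagated by free 1-D
#' diffusion with the liquid-phase diffusivity for a time `t_prime`: the
#' convolution of Laplace(lambda0) with a zero-mean Gaussian of variance
#' `s^2 = 2 * DeffL * t_prime`,
#'
#' `p(x) = exp(-b^2) * (erfcx(a - b) + erfcx(a + b)) / (4 lambda0)`,
#'
#' with `a = s/(sqrt(2) lambda0)`, `b = x/(sqrt(2) s)` and erfcx the
#' scaled complementary error function.  This form is finite for
#' `s^2/(2 lambda0^2)` up to at least 1e4 (the naive
#' `exp(s^2/2 lambda0^2) * erfc(...)` product overflows long before).
#' For the negative-argument branch (`b > a`) the identity
#' `exp(-b^2) erfcx(a-b) = 2 exp(a(a-2b)) - exp(-b^2) erfcx(b-a)` keeps
#' every factor bounded.
#'
#' Excess kurtosis before any rescale is
#' `3 * (2 lambda0^2)^2 / (2 lambda0^2 + s^2)^2`, interpolating from 3
#' (pure Laplace) to 0 (Gaussian); an affine rescale preserves it.
#'
#' @param x Displacement in um (vectorised).
#' @param t_prime Time since the critical time, seconds, nonnegative.
#' @param lambda0 Laplace scale of the initial condition, um, positive.
#' @param DeffL Liquid-phase diffusivity, um^2/s, positive.
#' @param rescale_to Optional target variance (um^2); the density is
#'   rescaled by the affine change of variable that preserves shape and
#'   unit mass.  `NULL` (default) leaves the natural variance
#'   `2*lambda0^2 + 2*DeffL*t_prime`.
#' @return Density values, per um.
#' @export
transition_pdf <- function(x, t_prime, lambda0, DeffL, rescale_to = NULL) {
  stopifnot(is.numeric(x), is.numeric(t_prime), length(t_prime) == 1L,
            is.numeric(lambda0), length(lambda0) == 1L,
            is.numeric(DeffL), length(DeffL) == 1L)
  if (!is.finite(t_prime) || t_prime < 0) stop("t_prime must be >= 0")
  if (lambda0 <= 0) stop("lambda0 must be positive")
  if (DeffL <= 0) stop("DeffL must be positive")
  if (!is.null(rescale_to)) {
    stopifnot(is.numeric(rescale_to), length(rescale_to) == 1L,
              rescale_to > 0)
    v0 <- 2 * lambda0^2 + 2 * DeffL * t_prime
    c0 <- sqrt(rescale_to / v0)
    return(transition_pdf(x / c0, t_prime, lambda0, DeffL) / c0)
  }
  s2 <- 2 * DeffL * t_prime
  if (s2 == 0) return(exp(-abs(x) / lambda0) / (2 * lambda0))
  s <- sqrt(s2)
  a <- s / (sqrt(2) * lambda0)
  b <- abs(x) / (sqrt(2) * s)   # even in x
  # exp(-b^2)*erfcx(a - b): bounded directly for b <= a, via the
  # reflection identity for b > a (exponent a*(a-2b) < -a^2 there).
  minus <- ifelse(b <= a,
                  exp(-b^2) * erfcx(a - b),
                  2 * exp(a * (a - 2 * b)) - exp(-b^2) * erfcx(b - a))
  plus <- exp(-b^2) * erfcx(a + b)
  (minus + plus) / (4 * lambda0)
}

#' Excess kurtosis of the transition density
#'
#' Closed form `3 * (2 lambda0^2)^2 / (2 lambda0^2 + 2 DeffL t_prime)^2`
#' (cumulants of the Laplace--Gaussian convolution); scale-invariant, so
#' unaffected by the observation rescale.
#'
#' @inheritParams transition_pdf
#' @return Excess kurtosis (3 at `t_prime = 0`, decreasing to 0).
#' @export
transition_kurtosis <- function(t_prime, lambda0, DeffL) {
  stopifnot(is.numeric(t_prime), all(t_prime >= 0),
            is.numeric(lambda0), length(lambda0) == 1L, lambda0 >= 0,
            is.numeric(DeffL), length(DeffL) == 1L, DeffL > 0)
  v_l <- 2 * lambda0^2
  3 * v_l^2 / (v_l + 2 * DeffL * t_prime)^2
}

#' Theoretical mean squared displacement of the two-regime mixture
#'
#' Averaging over the two equally likely phases gives a strictly linear
#' MSD, `2 * Davg * t` in 1-D and `6 * Davg * t` in 3-D -- normal
#' diffusion in the MSD sense at all times, regardless of the displacement
#' distribution's shape.
#'
#' @param t Time in seconds (vectorised), nonnegative.
#' @param phase A [phase_params()] object.
#' @param dims 1 or 3 (spatial dimension).
#' @return MSD in um^2.
#' @export
msd <- function(t, phase, dims = 1) {
  stopifnot(inherits(phase, "phase_params"), is.numeric(t), all(t >= 0))
  if (!(length(dims) == 1L && dims %in% c(1, 3)))
    stop("unsupported dims: must be 1 or 3")
  2 * dims * phase$Davg * t
}

#' Observed displacement density at a given time
#'
#' Dispatcher implementing the observation convention of the two-regime
#' model: up to the critical time `tc` the density is the Laplace law
#' rescaled to variance `2*Davg*t` (regime `"gas"`); after `tc` it is the
#' transition density started from the gas-like Laplace frozen at `tc`
#' (`lambda0 = sqrt(DeffG*tc)`), evolved with `DeffL` for `t - tc`, and
#' rescaled to variance `2*Davg*t` (regime `"transition"`).  Both branches
#' therefore have exactly the measured MSD at every time.
#'
#' @param x Displacement grid in um (vectorised); for a
#'   [displacement_pdf()] return it must be strictly increasing.
#' @param t Time in seconds, positive scalar.
#' @param phase A [phase_params()] object.
#' @param as_pdf Logical; `TRUE` wraps the result in a
#'   [displacement_pdf()] (requires `x` to be a grid spanning the support),
#'   `FALSE` (default) returns raw density values.
#' @return Density values per um, or a `displacement_pdf`.
#' @export
observed_pdf <- function(x, t, phase, as_pdf = FALSE) {
  stopifnot(inherits(phase, "phase_params"), is.numeric(x),
            is.numeric(t), length(t) == 1L)
  if (!is.finite(t) || t <= 0) stop("t must be positive")
  if (t <= phase$tc) {
    dens <- laplace_pdf(x, t, phase, rescale = TRUE)
    regime <- "gas"
  } else {
    lambda0 <- sqrt(phase$DeffG * phase$tc)
    dens <- transition_pdf(x, t - phase$tc, lambda0, phase$DeffL,
                           rescale_to = 2 * phase$Davg * t)
    regime <- "transition"
  }
  if (isTRUE(as_pdf)) displacement_pdf(x, dens, t, regime) else dens
}

#' Default evaluation grid for an observed density
#'
#' Symmetric grid wide and fine enough that the trapezoid mass of
#' [observed_pdf()] at time `t` is 1 within 1e-6: the Laplace branch
#' needs a half-width of ~45 decay lengths and a spacing well below the
#' decay length (the kink dominates the quadrature error,
#' ~`dx^2/(12 lambda^2)` relative); the smoother transition branch is
#' cheaper.
#'
#' @param phase A [phase_params()] object.
#' @param t Observation time in seconds, positive.
#' @param n Optional point-count override (odd keeps a node at 0).
#' @return Numeric grid in um.
#' @export
observed_grid <- function(phase, t, n = NULL) {
  stopifnot(inherits(phase, "phase_params"), is.numeric(t), t > 0)
  if (t <= phase$tc) {
    lam <- sqrt(phase$Davg * t)
    half <- 45 * lam
    if (is.null(n)) n <- 2L * ceiling(half / (lam / 1200)) %/% 2L + 1L
  } else {
    half <- 45 * sqrt(phase$Davg * t)
    if (is.null(n)) n <- 2L * ceiling(half / 5e-3) %/% 2L + 1L
  }
  seq(-half, half, length.out = as.integer(n))
}

#' Time for the transition density to become Gaussian
#'
#' Smallest `t_prime > 0` at which the transition density's excess
#' kurtosis falls below `threshold`.  Solving
#' `3*(2 lambda0^2)^2 / (2 lambda0^2 + 2 DeffL t_prime)^2 = threshold`
#' gives the closed form
#' `t_prime = lambda0^2 * (sqrt(3/threshold) - 1) / DeffL`.
#' With `lambda0 = sqrt(DeffG * tc)` this measures how long after the
#' critical time the observed density is operationally Gaussian.
#'
#' @param phase A [phase_params()] object; `lambda0` is taken as
#'   `sqrt(DeffG * tc)`.
#' @param threshold Excess-kurtosis cutoff, positive (default 0.05).
#' @return Time after the critical time, in seconds.
#' @export
gaussianity_time <- function(phase, threshold = 0.05) {
  stopifnot(inherits(phase, "phase_params"),
            is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  lambda0_sq <- phase$DeffG * phase$tc
  if (lambda0_sq == 0) return(0)
  if (threshold >= 3) return(0)
  lambda0_sq * (sqrt(3 / threshold) - 1) / phase$DeffL
}

#' Root-mean-squared relative distance between two clusters
#'
#' The RMS relative distance travelled, measured from the partner cluster,
#' under the effective diffusivity `Deff = D/Z^2`:
#' `sqrt(2 * (D/Z^2) * t)`.  This is the adiabatically growing scale that
#' sets the dry-friction drift and hence the Laplace scale.
#'
#' @param t Time in seconds (vectorised), nonnegative.
#' @param D Bare diffusivity, um^2/s.
#' @param Z Compressibility factor, positive.
#' @return RMS relative distance in um.
#' @export
rms_relative_distance <- function(t, D, Z) {
  stopifnot(is.numeric(t), all(t >= 0))
  sqrt(2 * effective_diffusivity(D, Z) * t)
}
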