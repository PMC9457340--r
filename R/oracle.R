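# Independent numerical ground truth for the closed-form densities:
# a Crank-Nicolson solver for the 1-D diffusion equation and a
# direct-quadrature Gaussian convolution.  Both are kept deliberately
# separate from the closed forms they validate.

#' Function sampled on a uniform grid
#'
#' @param x Uniform, strictly increasing grid (um).
#' @param values Nonnegative values (per um).
#' @return Object of class `grid_function` with fields `x`, `values`,
#'   `dx`, and the trapezoid `mass` at construction.
#' @export
grid_function <- function(x, values) {
  stopifnot(is.numeric(x), is.numeric(values),
            length(x) == length(values), length(x) >= 5L,
            all(is.finite(x)), all(is.finite(values)))
  dxs <- diff(x)
  if (any(dxs <= 0)) stop("x must be strictly increasing")
  if (max(abs(dxs - dxs[1])) > 1e-9 * dxs[1])
    stop("x must be uniformly spaced")
  if (any(values < 0)) stop("values must be nonnegative")
  structure(list(x = x, values = values, dx = dxs[1],
                 mass = trapz(x, values)),
            class = "grid_function")
}

#' Default grid for oracle computations
#'
#' Symmetric uniform grid with half-width `10 * sqrt(2 * Davg * t_final)`
#' (ten standard deviations of the widest PDF involved) and `2^12 + 1`
#' points.
#'
#' @param Davg Diffusivity setting the final standard deviation, um^2/s.
#' @param t_final Final time, seconds.
#' @param n Number of grid points (odd keeps a node at 0).
#' @param half_width Override the default half-width (um).
#' @return Numeric grid vector.
#' @export
oracle_grid <- function(Davg, t_final, n = 2^12 + 1, half_width = NULL) {
  if (is.null(half_width)) half_width <- 10 * sqrt(2 * Davg * t_final)
  seq(-half_width, half_width, length.out = n)
}

#' Crank--Nicolson solve of the 1-D diffusion equation
#'
#' Advances `du/dt = D d2u/dx2` from the initial condition `p0` for a time
#' `t_prime`, with homogeneous Dirichlet boundaries.  The first two steps
#' are backward Euler (Rannacher smoothing), which damps the spurious
#' high-frequency oscillations Crank--Nicolson produces from non-smooth
#' initial data such as the Laplace kink; the scheme is second-order
#' accurate away from those startup steps.
#'
#' Dirichlet boundaries are safe because every density of interest decays
#' exponentially; a guard refuses domains where the initial or final
#' boundary mass exceeds 1e-6 of the total.
#'
#' @param p0 A [grid_function()] initial condition.
#' @param D Diffusivity in um^2/s, positive.
#' @param t_prime Integration time in seconds, nonnegative.
#' @param dt Time step in seconds; default resolves `t_prime` into at
#'   least 400 steps.
#' @param expected_sd Standard deviation of the expected final density
#'   (um), used by the domain-size guard; default
#'   `sqrt(var(p0) + 2*D*t_prime)`.
#' @return A [grid_function()] at `t_prime`.
#' @export
solve_diffusion <- function(p0, D, t_prime, dt = NULL,
                            expected_sd = NULL) {
  stopifnot(inherits(p0, "grid_function"),
            is.numeric(D), length(D) == 1L, D > 0,
            is.numeric(t_prime), length(t_prime) == 1L, t_prime >= 0)
  if (t_prime == 0) return(p0)
  half_width <- (max(p0$x) - min(p0$x)) / 2
  if (is.null(expected_sd)) {
    m <- grid_moments(p0$x, p0$values)
    expected_sd <- sqrt(m$variance + 2 * D * t_prime)
  }
  if (half_width < 8 * expected_sd)
    stop(sprintf(
      "domain half-width %.3g um below 8 expected standard deviations %.3g um",
      half_width, 8 * expected_sd))
  # boundary-mass guard: edge values must be negligible
  edge <- max(p0$values[1], p0$values[length(p0$values)])
  if (edge * p0$dx > 1e-6 * p0$mass)
    stop("domain too small: boundary mass exceeds 1e-6 of the total")
  if (is.null(dt)) dt <- t_prime / 400
  n_steps <- max(2L, as.integer(ceiling(t_prime / dt)))
  dt_eff <- t_prime / n_steps
  vals <- cn_diffuse_cpp(p0$values, p0$dx, D, n_steps, dt_eff, 2L)
  vals[vals < 0] <- 0  # clip startup-level negative undershoot
  out <- grid_function(p0$x, vals)
  if (abs(out$mass - p0$mass) > 1e-6 * p0$mass)
    stop("mass leaked through the boundary: enlarge the domain")
  out
}

#' Direct-quadrature convolution with a Gaussian kernel
#'
#' Convolves a gridded density with a zero-mean Gaussian of the given
#' variance by discrete quadrature on the grid (FFT-accelerated open
#' convolution, centre segment retained).  Zero variance is the identity.
#' The kernel must be resolved: its standard deviation must be at least
#' `3 * dx`.
#'
#' @param p0 A [grid_function()].
#' @param kernel_variance Gaussian kernel variance in um^2, nonnegative.
#' @return A [grid_function()] holding the convolution on the same grid.
#' @export
convolve_quadrature <- function(p0, kernel_variance) {
  stopifnot(inherits(p0, "grid_function"),
            is.numeric(kernel_variance), length(kernel_variance) == 1L,
            kernel_variance >= 0)
  if (kernel_variance == 0) return(p0)
  s <- sqrt(kernel_variance)
  if (s < 3 * p0$dx)
    stop(sprintf(
      "kernel std %.3g um under-resolved: require >= 3 * dx = %.3g um",
      s, 3 * p0$dx))
  n <- length(p0$x)
  kx <- (seq_len(2L * n - 1L) - n) * p0$dx
  kern <- stats::dnorm(kx, sd = s) * p0$dx
  full <- stats::convolve(p0$values, rev(kern), type = "open")
  # open convolution of n and 2n-1 points has 3n-2 points; the aligned
  # centre segment is offset by n-1
  vals <- full[(n - 1L) + seq_len(n)]
  vals[vals < 0] <- 0
  grid_function(p0$x, vals)
}
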