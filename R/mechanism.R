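#' Microscopic interaction parameters
#'
#' Parameters of the interface layer: the dispersion energy and contact
#' distance of the attractive Lennard-Jones tail, the fluid density at the
#' interface (gas-like state) and in the gel-like phase, and the cluster
#' radius.  The modelled scenario has `rho_s < rho_L`: the density grows
#' monotonically from its interface value towards the gel-phase value with
#' distance.
#'
#' @param epsilon Dispersion energy in joules.
#' @param sigma Van der Waals contact distance in metres (closest approach
#'   of a fluid molecule to an interface molecule).
#' @param rho_s Fluid number density at the interface, m^-3.
#' @param rho_L Number density of the gel-like (incompressible) phase,
#'   m^-3; must exceed `rho_s`.
#' @param radius Cluster radius in metres.
#' @return An object of class `mechanism_params`.
#' @export
mechanism_params <- function(epsilon, sigma, rho_s, rho_L, radius) {
  p <- list(epsilon = epsilon, sigma = sigma, rho_s = rho_s,
            rho_L = rho_L, radius = radius)
  for (f in names(p)) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("invalid mechanism parameter: `", f,
           "` must be a single finite positive number")
  }
  if (rho_s >= rho_L)
    stop("invalid mechanism parameters: require rho_s < rho_L ",
         "(interface density below gel-phase density)")
  structure(p, class = "mechanism_params")
}

#' Attractive Lennard-Jones pair energy
#'
#' The long-range (attractive) part of the 6-12 Lennard-Jones potential,
#' `U(r) = -4 * epsilon * (sigma/r)^6`, modelling the weak dipole--dipole /
#' Van der Waals attraction between a molecule of the Brownian particle and
#' a fluid molecule.  Strictly negative, increasing monotonically to zero.
#'
#' @param r Intermolecular distance in metres (vectorised), positive.
#' @param p A [mechanism_params()] object.
#' @return Pair energy in joules.
#' @export
lj_attractive <- function(r, p) {
  stopifnot(inherits(p, "mechanism_params"), is.numeric(r))
  if (any(r <= 0)) stop("r must be positive")
  -4 * p$epsilon * (p$sigma / r)^6
}

#' Interface potential of a half-space of attracting molecules
#'
#' Energy of a fluid molecule a distance z from an interface carrying a
#' uniform density rho_s of Lennard-Jones attractors, in the long-range
#' limit where only the inverse-cube tail survives:
#' `V(z) = -(4*pi/3) * epsilon * sigma^6 * rho_s / z^3`.
#'
#' The prefactor is kept exactly as used by the phase-separation model.
#' Direct integration of [lj_attractive()] over a uniform half-space gives
#' the same `z^-3` law with prefactor `(2*pi/3) * epsilon * sigma^6 *
#' rho_s`; only the power law and the constancy of the prefactor are
#' physically load-bearing downstream (the profile's amplitude is absorbed
#' into the boundary densities).
#'
#' @param z Distance from the interface in metres (vectorised), positive.
#' @param p A [mechanism_params()] object.
#' @return Potential energy in joules (negative).
#' @export
interface_potential <- function(z, p) {
  stopifnot(inherits(p, "mechanism_params"), is.numeric(z))
  if (any(z <= 0)) stop("z must be positive")
  -(4 * pi / 3) * p$epsilon * p$sigma^6 * p$rho_s / z^3
}

#' Fluid density profile near a cluster
#'
#' Linearised Boltzmann--Gibbs profile of the gas-like fluid in the
#' interface potential: with `exp(-V/kBT) ~ 1 - V/kBT` for `|V| << kBT`,
#' the density interpolates between its interface value and the gel-phase
#' value as `rho(r) = rho_L + (rho_s - rho_L) * (sigma/r)^3` (the
#' interface potential's inverse-cube law carries straight through to the
#' density).  The radial coordinate is the mean relative distance from the
#' cluster centre.
#'
#' A diagnostic warning is emitted when the linearisation is used outside
#' its validity range (`|V|/kBT > 0.1` at the requested distance).
#'
#' @param r Radial distance in metres (vectorised), at least `sigma`.
#' @param p A [mechanism_params()] object.
#' @param T Temperature in kelvin.
#' @param linearised Logical; `FALSE` evaluates the full exponential
#'   profile `rho_L + (rho_s - rho_L) * (exp(-V/kBT) - 1) /
#'   (exp(-V(sigma)/kBT) - 1)` for diagnostic comparison.  The linearised
#'   form is the model's own.
#' @param kB Boltzmann constant, J/K.
#' @return Number density in m^-3.
#' @export
density_profile <- function(r, p, T, linearised = TRUE,
                            kB = 1.380649e-23) {
  stopifnot(inherits(p, "mechanism_params"), is.numeric(r),
            is.numeric(T), length(T) == 1L, T > 0)
  if (any(r < p$sigma)) stop("r must be >= sigma (contact distance)")
  V <- interface_potential(r, p)
  ratio <- abs(V) / (kB * T)
  if (any(ratio > 0.1))
    warning(sprintf(
      "linearised Boltzmann profile used where |V|/kBT = %.3g > 0.1; %s",
      max(ratio), "treat the profile as qualitative at these distances"))
  if (linearised) {
    p$rho_L + (p$rho_s - p$rho_L) * (p$sigma / r)^3
  } else {
    Vs <- interface_potential(p$sigma, p)
    p$rho_L + (p$rho_s - p$rho_L) *
      expm1(-V / (kB * T)) / expm1(-Vs / (kB * T))
  }
}

#' Radial gradient of the interaction-corrected particle number
#'
#' Treating the gas-like fluid as an ideal gas with modified particle count
#' Z*N (Z the compressibility factor), the spherically symmetric density
#' profile implies a purely radial gradient `d(Z N)/dr = -Z / r`.  This
#' gradient -- not a direct pair force -- is what couples two clusters.
#'
#' @param r Radial distance (vectorised), positive.  Any length unit; the
#'   result is in the reciprocal of that unit.
#' @param Z Compressibility factor, positive.
#' @return The (negative) gradient, per unit length.
#' @export
number_gradient <- function(r, Z) {
  stopifnot(is.numeric(r), is.numeric(Z))
  if (any(r <= 0)) stop("r must be positive")
  if (any(Z <= 0)) stop("Z must be positive")
  -Z / r
}

#' Attractive inter-cluster force
#'
#' The number-of-particles gradient across a cluster's cross-section
#' produces a net ideal-gas-law force of magnitude `kB*T / (r*Z)`, directed
#' radially inwards along the line joining the two clusters (attractive).
#' A cluster exerts no such force on itself: the self-field is spherically
#' symmetric.
#'
#' @param r Mean relative distance between the clusters in metres
#'   (vectorised), positive.
#' @param Z Compressibility factor, positive.
#' @param T Temperature in kelvin, positive.
#' @param units `"N"` for newtons (signed SI force along the separation
#'   unit vector) or `"kBT_per_um"` for the thermal units used by the
#'   Langevin layer.
#' @param kB Boltzmann constant, J/K.
#' @return Signed radial force (negative = attractive), in the requested
#'   units.
#' @export
cluster_force <- function(r, Z, T, units = c("N", "kBT_per_um"),
                          kB = 1.380649e-23) {
  units <- match.arg(units)
  stopifnot(is.numeric(r), is.numeric(Z), is.numeric(T))
  if (any(r <= 0)) stop("r must be positive")
  if (any(Z <= 0)) stop("Z must be positive")
  if (any(T <= 0)) stop("T must be positive")
  f_si <- -kB * T / (r * Z)           # r in m -> N
  switch(units,
         N = f_si,
         # kBT per um of separation measured in um: -1/((r/1e-6) * Z)
         kBT_per_um = -1 / ((r * 1e6) * Z))
}
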