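#' Physical parameters of a colloidal tracking experiment
#'
#' Container for the quantities entering the Stokes--Einstein relation:
#' absolute temperature, the bulk-water shear-viscosity reference, the
#' medium's viscosity expressed as a multiple of bulk water, the Brownian
#' particle radius, and the Boltzmann constant.  All fields are SI; unit
#' conversion to the micrometre--second system used everywhere else in the
#' package happens exactly once, in [einstein_diffusivity()].
#'
#' @param temperature Absolute temperature in kelvin.  Alternatively supply
#'   `temperature_C` (degrees Celsius) and leave this `NULL`.
#' @param temperature_C Temperature in degrees Celsius; converted with
#'   T/K = T/degC + 273.15.  Ignored when `temperature` is given.
#' @param eta_water Bulk-water shear viscosity reference in Pa s.  The
#'   default 1.0e-3 Pa s (1.0 mPa s) is a documented convention of this
#'   package, not a measured value at the default temperature.
#' @param viscosity_multiplier Medium viscosity as a dimensionless multiple
#'   of `eta_water`; lipid-bilayer tube experiments report values of order
#'   100.
#' @param radius Brownian particle radius in metres.
#' @param boltzmann Boltzmann constant in J/K (SI exact value by default).
#'
#' @return An object of class `physical_params`.
#' @examples
#' pp <- physical_params(temperature_C = 22, viscosity_multiplier = 100,
#'                       radius = 50e-9)
#' einstein_diffusivity(pp)
#' @export
physical_params <- function(temperature = NULL, temperature_C = NULL,
                            eta_water = 1.0e-3, viscosity_multiplier = 100,
                            radius = 50e-9, boltzmann = 1.380649e-23) {
  if (is.null(temperature)) {
    if (is.null(temperature_C))
      stop("supply `temperature` (K) or `temperature_C` (degrees Celsius)")
    temperature <- temperature_C + 273.15
  }
  p <- list(temperature = temperature, eta_water = eta_water,
            viscosity_multiplier = viscosity_multiplier,
            radius = radius, boltzmann = boltzmann)
  for (f in names(p)) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("invalid physical parameter: `", f,
           "` must be a single finite positive number")
  }
  structure(p, class = "physical_params")
}

#' @export
print.physical_params <- function(x, ...) {
  cat("<physical_params>\n")
  cat(sprintf("  temperature : %.2f K (%.2f degC)\n",
              x$temperature, x$temperature - 273.15))
  cat(sprintf("  viscosity   : %.3g mPa s (x%g bulk water at %.3g mPa s)\n",
              1e3 * x$eta_water * x$viscosity_multiplier,
              x$viscosity_multiplier, 1e3 * x$eta_water))
  cat(sprintf("  radius      : %.3g nm\n", 1e9 * x$radius))
  invisible(x)
}

#' Two-phase diffusivity parameters
#'
#' Bundles the bare diffusivity `D`, the compressibility factors of the
#' gas-like and liquid phases, the derived effective diffusivities
#' `DeffG = D/Z_G^2` and `DeffL = D/Z_L^2`, their equal-weight average
#' `Davg`, and the critical time `tc` at which the gas-like regime ends.
#' In the modelled regime the liquid compressibility factor is small
#' (`Z_L << 1`, strong attractive interactions), so the liquid phase is the
#' fast one: `DeffL > DeffG`.
#'
#' @param D Bare diffusivity in um^2/s.
#' @param Z_L Liquid-phase compressibility factor (dimensionless, > 0).
#' @param Z_G Gas-like-phase compressibility factor; 1 treats the gas-like
#'   phase as ideal.
#' @param tc Critical time in seconds at which the gas-like phase ends.
#'
#' @return An object of class `phase_params` with fields `D`, `Z_G`, `Z_L`,
#'   `DeffG`, `DeffL`, `Davg`, `tc`.
#' @seealso [infer_liquid_phase()] for constructing the object from a
#'   measured `Davg`.
#' @examples
#' phase_params(D = 0.014, Z_L = 0.13, tc = 4)
#' @export
phase_params <- function(D, Z_L, Z_G = 1, tc = 4) {
  stopifnot(is.numeric(D), length(D) == 1L, is.finite(D),
            is.numeric(Z_L), length(Z_L) == 1L, is.finite(Z_L),
            is.numeric(Z_G), length(Z_G) == 1L, is.finite(Z_G),
            is.numeric(tc), length(tc) == 1L, is.finite(tc))
  if (D <= 0) stop("invalid phase parameter: D must be positive")
  if (Z_L <= 0 || Z_G <= 0)
    stop("invalid phase parameter: compressibility factors must be positive")
  if (tc <= 0) stop("invalid phase parameter: tc must be positive")
  DeffG <- effective_diffusivity(D, Z_G)
  DeffL <- effective_diffusivity(D, Z_L)
  structure(list(D = D, Z_G = Z_G, Z_L = Z_L,
                 DeffG = DeffG, DeffL = DeffL,
                 Davg = average_diffusivity(DeffG, DeffL), tc = tc),
            class = "phase_params")
}

#' @export
print.phase_params <- function(x, ...) {
  cat("<phase_params>  (diffusivities in um^2/s)\n")
  cat(sprintf("  D = %.4g   Z_G = %.4g   Z_L = %.4g\n", x$D, x$Z_G, x$Z_L))
  cat(sprintf("  DeffG = %.4g   DeffL = %.4g   Davg = %.4g   tc = %.4g s\n",
              x$DeffG, x$DeffL, x$Davg, x$tc))
  invisible(x)
}

#' Stokes--Einstein diffusivity, optionally with extensional viscosity
#'
#' For a sphere of radius R in a fluid of shear viscosity eta at
#' temperature T, the bare diffusivity is `D = kB*T / (6*pi*eta*R)`.
#' In a compressible medium the resistance is set by the extensional
#' viscosity, which for a Newtonian fluid is `eta_e = 3*eta`, giving
#' `D = kB*T / (18*pi*eta*R)`.  The extensional form is the default because
#' the two-phase model targets compressible media.
#'
#' @param params A [physical_params()] object.
#' @param extensional Logical; `TRUE` (default) uses the 18*pi*eta*R
#'   denominator, `FALSE` the classical 6*pi*eta*R.
#' @return Diffusivity in um^2/s.
#' @examples
#' pp <- physical_params(temperature_C = 22, viscosity_multiplier = 100,
#'                       radius = 50e-9)
#' einstein_diffusivity(pp)                      # ~0.014 um^2/s
#' einstein_diffusivity(pp, extensional = FALSE) # 3x larger
#' @export
einstein_diffusivity <- function(params, extensional = TRUE) {
  if (!inherits(params, "physical_params"))
    params <- do.call(physical_params, as.list(params))
  eta <- params$eta_water * params$viscosity_multiplier
  denom_factor <- if (isTRUE(extensional)) 18 else 6
  D_si <- params$boltzmann * params$temperature /
    (denom_factor * pi * eta * params$radius)   # m^2/s
  D_si * 1e12                                   # -> um^2/s
}

#' Effective diffusivity from the compressibility factor
#'
#' A Van der Waals gas behaves as an ideal gas with a modified particle
#' count Z*N; carrying Z through the inter-cluster force halves into the
#' Langevin drift yields an effective diffusivity `Deff = D / Z^2`.
#' Attractive interactions (Z < 1) therefore *increase* the effective
#' diffusivity.
#'
#' @param D Bare diffusivity (um^2/s), positive.
#' @param Z Compressibility factor, positive.
#' @return `D / Z^2` in um^2/s.
#' @export
effective_diffusivity <- function(D, Z) {
  stopifnot(is.numeric(D), is.numeric(Z))
  if (any(D <= 0)) stop("D must be positive")
  if (any(Z == 0)) stop("Z must be nonzero (division by Z^2)")
  if (any(Z < 0)) stop("Z must be positive")
  D / Z^2
}

#' Equal-weight average of the two phases' effective diffusivities
#'
#' The gas-like and liquid phases are two equally likely states of the
#' system, so the observed mean squared displacement grows with the
#' equal-weight mean `Davg = 0.5*(DeffG + DeffL)`; `Davg` is what a
#' single-particle-tracking experiment actually measures.
#'
#' @param DeffG Gas-like-phase effective diffusivity (um^2/s).
#' @param DeffL Liquid-phase effective diffusivity (um^2/s).
#' @return `0.5 * (DeffG + DeffL)` in um^2/s.
#' @export
average_diffusivity <- function(DeffG, DeffL) {
  stopifnot(is.numeric(DeffG), is.numeric(DeffL))
  if (any(DeffG < 0) || any(DeffL < 0))
    stop("effective diffusivities must be nonnegative")
  0.5 * (DeffG + DeffL)
}

#' Infer the liquid-phase diffusivity from a measured average
#'
#' Inverts the equal-weight average under the ideal-gas-like approximation
#' for the gas phase (`Z_G = 1` by default, so `DeffG = D/Z_G^2 = D`):
#' `DeffL = 2*Davg - D/Z_G^2` and `Z_L = sqrt(D / DeffL)`.  The measured
#' `Davg` must exceed `0.5 * D / Z_G^2`; otherwise no liquid phase faster
#' than the gas-like phase exists and the motion is regular Brownian
#' diffusion, which this two-phase inversion cannot describe.
#'
#' @param Davg Measured average diffusivity (um^2/s).
#' @param D Bare diffusivity from [einstein_diffusivity()] (um^2/s).
#' @param Z_G Gas-like-phase compressibility factor (default 1, ideal gas).
#' @param tc Critical time in seconds, stored in the result.
#' @return A [phase_params()] object.
#' @examples
#' infer_liquid_phase(Davg = 0.40, D = 0.014)  # DeffL ~ 0.79, Z_L ~ 0.13
#' @export
infer_liquid_phase <- function(Davg, D, Z_G = 1, tc = 4) {
  stopifnot(is.numeric(Davg), length(Davg) == 1L, is.finite(Davg),
            is.numeric(D), length(D) == 1L, is.finite(D))
  if (Davg <= 0 || D <= 0) stop("Davg and D must be positive")
  DeffG <- effective_diffusivity(D, Z_G)
  if (Davg <= 0.5 * DeffG)
    stop("no phase separation: Davg <= 0.5 * D/Z_G^2 signals regular ",
         "Brownian motion (no liquid phase faster than the gas-like phase)")
  DeffL <- 2 * Davg - DeffG
  Z_L <- sqrt(D / DeffL)
  phase_params(D = D, Z_L = Z_L, Z_G = Z_G, tc = tc)
}
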