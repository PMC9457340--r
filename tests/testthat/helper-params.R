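# Shared fixtures: the bead-on-bilayer-tube experimental conditions and
# small numerical helpers.  All fixtures are built in code.

bead_physical <- function(multiplier = 100) {
  physical_params(temperature_C = 22, eta_water = 1.0e-3,
                  viscosity_multiplier = multiplier, radius = 50e-9)
}

# Full derived phase-parameter set from the experiment's printed inputs:
# Davg = 0.40 um^2/s, tc = 4 s, ideal gas-like phase.
bead_phase <- function() {
  infer_liquid_phase(Davg = 0.40, D = einstein_diffusivity(bead_physical()),
                     Z_G = 1, tc = 4)
}

# Dimensionless dry-friction testbed: D = 1, Z = 1 so DeffG = 1, and the
# fixed drift scale lambda = 1 reproduces the unit Laplace stationary law.
unit_phase <- function(tc = 1) phase_params(D = 1, Z_L = 1, Z_G = 1, tc = tc)

trapint <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

grid_mom <- function(x, dens) {
  mass <- trapint(x, dens)
  mu <- trapint(x, x * dens) / mass
  v <- trapint(x, (x - mu)^2 * dens) / mass
  m4 <- trapint(x, (x - mu)^4 * dens) / mass
  list(mass = mass, variance = v, excess_kurtosis = m4 / v^2 - 3)
}

laplace_cdf <- function(q, lambda = 1) {
  ifelse(q < 0, 0.5 * exp(q / lambda), 1 - 0.5 * exp(-q / lambda))
}

# one-sample Kolmogorov-Smirnov distance against a CDF function
ks_dist <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  f <- cdf(x)
  max(abs(f - seq_len(n) / n), abs(f - (seq_len(n) - 1) / n))
}
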