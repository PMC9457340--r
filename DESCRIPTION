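Package: bnyg
Title: Two-Regime Phase-Separation Model of Brownian yet Non-Gaussian
    Diffusion
Version: 0.1.0
Authors@R:
    person("bnyg", "maintainers", email = "bnyg@example.org",
           role = c("aut", "cre"))
Description: Models Brownian yet non-Gaussian diffusion -- linear-in-time
    mean squared displacement with a Laplace (double-exponential)
    displacement distribution -- as observed in single-particle tracking
    of colloidal beads on lipid-bilayer tubes.  Implements the microscopic
    interaction layer (attractive Lennard-Jones tail, inverse-cube
    interface potential, fluid density profile, radial inter-cluster
    force), the overdamped Langevin process with dry-friction drift and
    its closed-form propagator, the Laplace and Laplace-Gaussian
    transition displacement densities, Stokes-Einstein diffusivity with
    extensional viscosity, the compressibility-factor diffusivity algebra,
    a seeded Euler-Maruyama simulator of the two-regime process, and
    independent numerical oracles (Crank-Nicolson diffusion solver,
    direct-quadrature convolution).  A command-line interface reproduces
    the worked application to beads on phospholipid-bilayer tubes and
    scores user-supplied displacement histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    optparse,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
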