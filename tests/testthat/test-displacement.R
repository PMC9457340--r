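test_that("dry-friction propagator is a unit-mass density with the Laplace stationary limit", {
  g <- seq(-40, 40, length.out = 80001)
  for (tau in c(0.1, 1, 10)) for (r0 in c(0, 1)) {
    P <- dry_friction_propagator(g, tau, r0)
    expect_true(all(P >= 0))
    expect_lt(abs(trapint(g, P) - 1), 1e-6)
  }
  # tau -> Inf: Boltzmann-Gibbs law of the linear potential, (1/2) e^-|r|
  gs <- seq(-30, 30, length.out = 8001)
  expect_lt(max(abs(dry_friction_propagator(gs, 50, 0) -
                      0.5 * exp(-abs(gs)))), 1e-3)
  expect_error(dry_friction_propagator(0, 0), "positive")
  expect_error(dry_friction_propagator(0, -1), "positive")
})

test_that("propagator agrees with an Euler-Maruyama ensemble at tau = 1", {
  # scaled down from the 1e5-path acceptance check to keep the unit suite
  # fast; the full-size version runs in test-acceptance.R
  ens <- simulate_ensemble(sim_config(unit_phase(), n_paths = 2e4,
                                      dt = 0.002, t_max = 1, seed = 5,
                                      drift_mode = "fixed",
                                      record_stride = 500L,
                                      lambda_fixed = 1))
  x <- ens$positions[, ncol(ens$positions)]
  g <- seq(-12, 12, length.out = 24001)
  P <- dry_friction_propagator(g, 1, 0)
  cdf_fun <- approxfun(g, cumsum(c(0, diff(g) * (head(P, -1) + tail(P, -1)) / 2)),
                       rule = 2)
  expect_lt(ks_dist(x, cdf_fun), 0.015)
})

test_that("Laplace phase density: peak, slope, variance and rescaling convention", {
  ph <- bead_phase()
  # rescaled scale: lambda = sqrt(Davg * t); peak = 1/(2 lambda)
  expect_equal(laplace_pdf(0, 3, ph), 1 / (2 * sqrt(1.2)))
  expect_equal(round(laplace_pdf(0, 3, ph), 4), 0.4564)
  # unrescaled branch uses the gas-like diffusivity
  expect_equal(laplace_pdf(0, 3, ph, rescale = FALSE),
               1 / (2 * sqrt(ph$DeffG * 3)))
  # log density exactly linear in |x| with slope -1/lambda
  x <- seq(0.05, 3, by = 0.05)
  lam <- sqrt(ph$Davg * 2)
  sl <- unname(coef(lm(log(laplace_pdf(x, 2, ph)) ~ x))[2])
  expect_equal(sl, -1 / lam, tolerance = 1e-9)
  # analytic variance 2 lambda^2 = 2 Davg t via grid moments
  for (t in c(0.06, 1, 4)) {
    lam <- sqrt(ph$Davg * t)
    g <- seq(-45 * lam, 45 * lam, length.out = 27001)
    expect_equal(grid_mom(g, laplace_pdf(g, t, ph))$variance,
                 2 * ph$Davg * t, tolerance = 1e-6)
  }
  expect_error(laplace_pdf(0, 0, ph), "positive")
})

test_that("transition density limits: delta kernel and Gaussian", {
  lam0 <- 0.4; D <- 0.79
  x <- seq(-6, 6, length.out = 2001)
  # t' -> 0 recovers the Laplace initial condition
  expect_equal(transition_pdf(x, 0, lam0, D),
               exp(-abs(x) / lam0) / (2 * lam0))
  # the convolution deviates from the Laplace by O(s/lambda0) at the
  # kink, so t' must make s = sqrt(2 D t') truly negligible
  expect_lt(max(abs(transition_pdf(x, 1e-18, lam0, D) -
                      exp(-abs(x) / lam0) / (2 * lam0))), 1e-8)
  # lam0 -> 0 recovers the free-diffusion Gaussian
  tp <- 2; s <- sqrt(2 * D * tp)
  expect_lt(max(abs(transition_pdf(x, tp, 1e-4 * s, D) -
                      dnorm(x, sd = s))), 1e-6)
  expect_error(transition_pdf(0, -1, lam0, D), "t_prime")
  expect_error(transition_pdf(0, 1, 0, D), "lambda0")
})

test_that("transition density is overflow-safe, symmetric, and unit mass", {
  lam0 <- 0.5; D <- 0.79
  # contract: finite for s^2 / (2 lam0^2) up to 1e4
  tp_big <- 1e4 * 2 * lam0^2 / (2 * D)
  v <- transition_pdf(c(0, 1, 5, 50, 500), tp_big, lam0, D)
  expect_true(all(is.finite(v)) && all(v >= 0))
  x <- seq(0.1, 8, length.out = 50)
  expect_identical(transition_pdf(x, 1.3, lam0, D),
                   transition_pdf(-x, 1.3, lam0, D))
  for (tp in c(0.1, 1.8, 20)) {
    s <- sqrt(2 * D * tp)
    half <- 40 * lam0 + 8 * s
    g <- seq(-half, half, length.out = 2^15 + 1)
    expect_lt(abs(trapint(g, transition_pdf(g, tp, lam0, D)) - 1), 1e-6)
  }
})

test_that("transition density equals the direct Laplace x Gaussian quadrature on random draws", {
  set.seed(31)
  for (i in 1:6) {
    lam0 <- runif(1, 0.3, 1)
    s <- lam0 * runif(1, 0.6, 3)
    D <- runif(1, 0.2, 2)
    tp <- s^2 / (2 * D)
    half <- 10 * sqrt(2 * lam0^2 + s^2) + 10 * lam0
    g <- seq(-half, half, length.out = 2^15 + 1)
    p0 <- grid_function(g, exp(-abs(g) / lam0) / (2 * lam0))
    conv <- convolve_quadrature(p0, s^2)
    expect_lt(max(abs(conv$values - transition_pdf(g, tp, lam0, D))), 1e-6)
  }
})

test_that("kurtosis closed form matches grid moments and drives the Gaussianization time", {
  set.seed(12)
  for (i in 1:5) {
    lam0 <- runif(1, 0.2, 0.8); D <- runif(1, 0.3, 1.5)
    tp <- runif(1, 0.2, 3)
    s <- sqrt(2 * D * tp)
    half <- 45 * lam0 + 10 * s
    g <- seq(-half, half, length.out = 2^15 + 1)
    m <- grid_mom(g, transition_pdf(g, tp, lam0, D))
    expect_equal(m$variance, 2 * lam0^2 + s^2, tolerance = 1e-6)
    expect_equal(m$excess_kurtosis, transition_kurtosis(tp, lam0, D),
                 tolerance = 1e-4)
  }
  expect_equal(transition_kurtosis(0, 0.3, 1), 3)

  ph <- bead_phase()
  tstar <- gaussianity_time(ph, threshold = 0.05)
  lam0 <- sqrt(ph$DeffG * ph$tc)
  # exact root of the closed form
  expect_equal(transition_kurtosis(tstar, lam0, ph$DeffL), 0.05)
  expect_gt(transition_kurtosis(tstar * 0.99, lam0, ph$DeffL), 0.05)
  # already-Gaussian threshold and degenerate cases
  expect_equal(gaussianity_time(ph, threshold = 3), 0)
  # monotone decreasing in DeffL: faster liquid -> faster Gaussianization
  t1 <- gaussianity_time(phase_params(D = 0.014, Z_L = 0.2, tc = 4))
  t2 <- gaussianity_time(phase_params(D = 0.014, Z_L = 0.1, tc = 4))
  expect_gt(t1, t2)
})

test_that("theoretical MSD of the mixture is linear with the 1-D/3-D ratio 3", {
  ph <- bead_phase()
  expect_equal(msd(0, ph), 0)
  expect_equal(msd(1, ph, dims = 1), 0.8)          # 2 * 0.40 * 1
  t <- c(0.1, 1, 7)
  expect_equal(msd(t, ph, dims = 3) / msd(t, ph, dims = 1), rep(3, 3))
  expect_error(msd(1, ph, dims = 2), "unsupported")
})

test_that("observed_pdf dispatches on tc and always carries the measured variance", {
  ph <- bead_phase()
  # gas branch at t = 3 s, transition branch at t = 5.8 s
  p3 <- observed_pdf(observed_grid(ph, 3), 3, ph, as_pdf = TRUE)
  expect_s3_class(p3, "displacement_pdf")
  expect_identical(p3$regime_label, "gas")
  m3 <- grid_mom(p3$grid, p3$density)
  expect_lt(abs(m3$mass - 1), 1e-6)
  expect_equal(m3$variance, 2 * ph$Davg * 3, tolerance = 1e-6)
  expect_equal(m3$excess_kurtosis, 3, tolerance = 1e-4)

  p6 <- observed_pdf(observed_grid(ph, 5.8), 5.8, ph, as_pdf = TRUE)
  expect_identical(p6$regime_label, "transition")
  m6 <- grid_mom(p6$grid, p6$density)
  expect_lt(abs(m6$mass - 1), 1e-6)
  expect_equal(m6$variance, 2 * ph$Davg * 5.8, tolerance = 1e-6)
  k6 <- m6$excess_kurtosis
  expect_gt(k6, 0); expect_lt(k6, 3)
  # kurtosis decreases strictly after tc and heads towards 0
  lam0 <- sqrt(ph$DeffG * ph$tc)
  ks <- transition_kurtosis(c(0.5, 1.8, 5, 50), lam0, ph$DeffL)
  expect_true(all(diff(ks) < 0))
  expect_lt(ks[4], 1e-4)
  expect_error(observed_pdf(0, -2, ph), "positive")
})

test_that("RMS relative distance follows the effective-diffusivity square-root law", {
  expect_equal(rms_relative_distance(0, 1, 0.5), 0)
  expect_equal(rms_relative_distance(4, 1, 0.5),
               2 * rms_relative_distance(1, 1, 0.5))
  expect_equal(rms_relative_distance(2, 1, 0.25),
               2 * rms_relative_distance(2, 1, 0.5))
  expect_error(rms_relative_distance(1, 1, 0), "nonzero")
})

test_that("displacement_pdf container enforces mass, positivity and grid order", {
  x <- seq(-5, 5, length.out = 501)
  d <- dnorm(x)
  expect_s3_class(displacement_pdf(x, d, 1, "gas"), "displacement_pdf")
  expect_error(displacement_pdf(x, 2 * d, 1, "gas"), "mass")
  expect_error(displacement_pdf(x, -d, 1, "gas"), "nonnegative")
  expect_error(displacement_pdf(rev(x), d, 1, "gas"), "increasing")
  m <- pdf_moments(displacement_pdf(x, d, 1, "mixture"))
  expect_equal(m$variance, 1, tolerance = 1e-4)
})
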