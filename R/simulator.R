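#' Configuration of the two-regime Langevin simulation
#'
#' Validated bundle of Euler--Maruyama settings.  The integrator works in
#' um and seconds throughout.  Two drift modes exist:
#'
#' * `"adiabatic"` (default): gas-like paths carry the dry-friction drift
#'   `-mu(t) sgn(x)` with `mu(t) = DeffG / lambda(t)` and the slowly
#'   growing scale `lambda(t) = sqrt(DeffG * t)` recomputed every step
#'   (floored at `lambda(dt)`), switching to free diffusion with `DeffL`
#'   at the critical time `tc`; liquid paths are free diffusion with
#'   `DeffL` throughout.  Each path is assigned gas or liquid with
#'   probability 1/2, permanently (the equal-weight two-state mixture; a
#'   per-step switch would change the mixture MSD).
#' * `"fixed"`: every path is a gas-like path with constant scale
#'   `lambda_fixed` and no regime switch -- the stationary-law testbed.
#'
#' The drift magnitude and noise amplitude are parameterised directly by
#' `(DeffG, lambda)`; the microscopic diffusivity of the dry-friction
#' process is set equal to `DeffG` since only their ratio is observable at
#' the displacement-distribution level.
#'
#' @param phase A [phase_params()] object.
#' @param n_paths Number of paths (>= 1).
#' @param dt Time step in seconds; must satisfy `dt <= 0.01 * tc`.
#' @param t_max Final time in seconds.
#' @param seed Integer RNG seed.
#' @param drift_mode `"adiabatic"` or `"fixed"`.
#' @param record_stride Store every `record_stride`-th step (plus t = 0).
#' @param lambda_fixed Constant Laplace scale in um for `"fixed"` mode;
#'   defaults to `sqrt(DeffG * tc)`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(phase, n_paths = 1e4, dt = 1e-3, t_max = 8,
                       seed = 1L, drift_mode = c("adiabatic", "fixed"),
                       record_stride = 100L, lambda_fixed = NULL) {
  drift_mode <- match.arg(drift_mode)
  stopifnot(inherits(phase, "phase_params"),
            is.numeric(n_paths), length(n_paths) == 1L, n_paths >= 1,
            is.numeric(dt), length(dt) == 1L, dt > 0,
            is.numeric(t_max), length(t_max) == 1L, t_max > 0,
            is.numeric(seed), length(seed) == 1L,
            is.numeric(record_stride), record_stride >= 1)
  if (dt > 0.01 * phase$tc)
    stop(sprintf("dt = %g too large: require dt <= 0.01 * tc = %g",
                 dt, 0.01 * phase$tc))
  if (is.null(lambda_fixed)) lambda_fixed <- sqrt(phase$DeffG * phase$tc)
  if (drift_mode == "fixed") {
    # drift-step stability: mu*dt < 0.1*lambda with mu = DeffG/lambda
    dt_max <- 0.1 * lambda_fixed^2 / phase$DeffG
    if (dt >= dt_max)
      stop(sprintf(
        "dt = %g unstable for fixed drift scale lambda = %g: require dt < %g",
        dt, lambda_fixed, dt_max))
  }
  structure(list(phase = phase, n_paths = as.integer(n_paths), dt = dt,
                 t_max = t_max, seed = as.integer(seed),
                 drift_mode = drift_mode,
                 record_stride = as.integer(record_stride),
                 lambda_fixed = lambda_fixed),
            class = "sim_config")
}

#' Simulate a seeded ensemble of two-regime trajectories
#'
#' Runs the Euler--Maruyama integrator described in [sim_config()].  The
#' drift is evaluated at the pre-step position (no higher-order scheme:
#' the dry-friction drift is non-smooth at 0, where `sgn(0) = 0`).  All
#' paths start at the origin.  Fixed seed gives a bitwise-identical
#' ensemble on rerun.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `trajectory_ensemble`: list with `times`
#'   (seconds), `positions` (paths x times matrix, um), `regime`
#'   (character per path, `"gas"`/`"liquid"`), `seed`, and the `config`.
#' @export
simulate_ensemble <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ph <- config$phase
  n_steps <- as.integer(round(config$t_max / config$dt))
  if (n_steps < config$record_stride)
    stop("t_max shorter than one recording stride")
  set.seed(config$seed)
  regime_int <- if (config$drift_mode == "fixed") {
    integer(config$n_paths)                       # all gas
  } else {
    as.integer(stats::runif(config$n_paths) < 0.5)  # 1 = liquid, p = 0.5
  }
  pos <- em_simulate_cpp(regime_int, config$dt, n_steps,
                         config$record_stride, ph$DeffG, ph$DeffL, ph$tc,
                         config$drift_mode == "adiabatic",
                         config$lambda_fixed)
  times <- seq(0L, n_steps %/% config$record_stride) *
    (config$record_stride * config$dt)
  structure(list(times = times, positions = pos,
                 regime = c("gas", "liquid")[regime_int + 1L],
                 seed = config$seed, config = config),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf(
    "<trajectory_ensemble> %d paths (%d gas / %d liquid), %d times to %g s, seed %d\n",
    nrow(x$positions), sum(x$regime == "gas"), sum(x$regime == "liquid"),
    length(x$times), max(x$times), x$seed))
  invisible(x)
}

#' Per-time summaries of a trajectory ensemble
#'
#' Pooled (equal-weight over both regimes, i.e. over all paths) mean
#' squared displacement, excess kurtosis, and a unit-mass displacement
#' histogram at each requested time.
#'
#' @param ens A [simulate_ensemble()] result.
#' @param times Times to summarise, each matching a recorded time within
#'   half a recording interval.
#' @param breaks Passed to [graphics::hist()]-style binning via
#'   [base::cut()]; number of equal-width bins for the histogram.
#' @return A list with `summary` (data.frame: `time`, `msd`,
#'   `excess_kurtosis`, `n`) and `histograms` (list of data.frames with
#'   `mid`, `density`).
#' @export
ensemble_stats <- function(ens, times = NULL, breaks = 101L) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  if (nrow(ens$positions) == 0L) stop("empty ensemble")
  if (is.null(times)) times <- ens$times[-1L]
  # match requested times to recorded ones, tolerating only float noise
  rec_dt <- if (length(ens$times) > 1L) diff(ens$times[1:2]) else 1
  idx <- vapply(times, function(t) {
    j <- which.min(abs(ens$times - t))
    if (abs(ens$times[j] - t) > 1e-3 * rec_dt)
      stop(sprintf("time %g s not recorded in the ensemble", t))
    j
  }, integer(1))
  hists <- vector("list", length(idx))
  out <- data.frame(time = ens$times[idx], msd = NA_real_,
                    excess_kurtosis = NA_real_, n = nrow(ens$positions))
  for (k in seq_along(idx)) {
    x <- ens$positions[, idx[k]]
    m2 <- mean(x^2)
    out$msd[k] <- m2
    out$excess_kurtosis[k] <- if (m2 > 0) mean(x^4) / m2^2 - 3 else NA_real_
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    hists[[k]] <- data.frame(mid = h$mids, density = h$density)
  }
  list(summary = out, histograms = hists)
}

#' Recover the average diffusivity from an ensemble's MSD
#'
#' Ordinary least squares of the pooled MSD against `2 t` through the
#' origin (the 1-D linear-MSD law of the two-regime mixture), returning
#' the slope as the `Davg` estimate with its standard error.
#'
#' The fit is restricted by default to recorded times in `(0, tc]`: the
#' equal-weight mixture law MSD = `2 Davg t` holds while both phases
#' coexist; after the critical time the gas-like phase has ended and the
#' pooled MSD slope crosses over towards `2 DeffL`.  Pass explicit
#' `times` to override.
#'
#' @param ens A [simulate_ensemble()] result.
#' @param times Optional subset of recorded times to use (default: all
#'   recorded times in `(0, tc]`).
#' @return List with `Davg` (um^2/s), `se`, and the fitted `msd`
#'   data.frame.
#' @export
fit_davg <- function(ens, times = NULL) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  if (is.null(times) && !is.null(ens$config))
    times <- ens$times[ens$times > 0 & ens$times <= ens$config$phase$tc]
  st <- ensemble_stats(ens, times)$summary
  st <- st[st$time > 0, , drop = FALSE]
  if (nrow(st) < 2L || length(unique(st$time)) < 2L)
    stop("need at least two distinct positive recorded times")
  fit <- stats::lm(msd ~ 0 + I(2 * time), data = st)
  # vcov warns on an exactly collinear (noiseless) fit; se is then 0
  se <- suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[1]))
  list(Davg = unname(stats::coef(fit)[1]), se = se, msd = st)
}
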