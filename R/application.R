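# Worked application: colloidal beads on phospholipid-bilayer tubes.
# Reproduces the derived scalar chain (bare diffusivity -> liquid-phase
# inversion -> Gaussianization time), emits model displacement curves on
# figure-style axes, and scores user displacement histograms with a
# fixed-intercept regression.

#' Default configuration of the bead-on-bilayer-tube application
#'
#' The printed experimental conditions: 22 degC, medium viscosity 100x
#' bulk water (1.0 mPa s reference), bead radius 50 nm, measured average
#' diffusivity 0.40 um^2/s, critical time 4 s, ideal gas-like phase
#' (Z_G = 1), and a 20 percent viscosity increase for the
#' cholesterol-stiffened control.
#'
#' @return Nested list with `physical` and `phase` blocks, the format
#'   accepted by [reproduce_application()] and [read_config()].
#' @export
default_application_config <- function() {
  list(
    physical = list(temperature_C = 22, water_viscosity_mPas = 1.0,
                    viscosity_multiplier = 100, radius_nm = 50),
    phase = list(Davg_um2s = 0.40, tc_s = 4, Z_G = 1),
    cholesterol_viscosity_factor = 1.2
  )
}

#' Read an application configuration file
#'
#' Accepts YAML (`.yml`/`.yaml`) or JSON.  Missing blocks or fields fall
#' back to [default_application_config()].
#'
#' @param path Path to the configuration file, or `NULL` for defaults.
#' @return Configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_application_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (blk in c("physical", "phase")) {
    if (!is.null(user[[blk]]))
      cfg[[blk]][names(user[[blk]])] <- user[[blk]]
  }
  if (!is.null(user$cholesterol_viscosity_factor))
    cfg$cholesterol_viscosity_factor <- user$cholesterol_viscosity_factor
  cfg
}

config_to_physical <- function(cfg) {
  ph <- cfg$physical
  need <- c("temperature_C", "water_viscosity_mPas",
            "viscosity_multiplier", "radius_nm")
  miss <- need[!vapply(need, function(f)
    is.numeric(ph[[f]]) && length(ph[[f]]) == 1L, logical(1))]
  if (length(miss))
    stop("config error: missing or non-numeric physical inputs: ",
         paste(miss, collapse = ", "))
  physical_params(temperature_C = ph$temperature_C,
                  eta_water = ph$water_viscosity_mPas * 1e-3,
                  viscosity_multiplier = ph$viscosity_multiplier,
                  radius = ph$radius_nm * 1e-9)
}

#' Reproduce the worked application
#'
#' Runs the full derived-scalar chain for a configured experiment:
#' extensional-viscosity Stokes--Einstein bare diffusivity `D`; inversion
#' of the measured average diffusivity for the liquid phase (`DeffL`,
#' `Z_L`); the cholesterol-control diffusivity at increased viscosity
#' (regular Brownian motion, no phase separation); the Gaussianization
#' time after `tc`; and model displacement curves at the requested times.
#'
#' @param config Configuration list as from [read_config()]; `NULL` uses
#'   [default_application_config()].
#' @param curve_times Times (s) at which model curves are produced.
#' @param grid_n Points per curve grid; `NULL` (default) picks a
#'   resolution fine enough for the unit-mass tolerance of
#'   [displacement_pdf()] on each branch (the Laplace kink needs
#'   `dx` well below its decay length).
#' @param threshold Excess-kurtosis cutoff for the Gaussianization time.
#' @return Object of class `bnyg_report`: list with `params`
#'   (physical), `phase` ([phase_params()]), scalars `D`, `D_cholesterol`,
#'   `DeffL`, `Z_L`, `Davg`, `tc`, `gaussianity_time_s`, `threshold`, and
#'   `curves` (named list of [displacement_pdf()]).
#' @export
reproduce_application <- function(config = NULL,
                                  curve_times = c(0.06, 0.6, 3, 5.8),
                                  grid_n = NULL, threshold = 0.05) {
  if (is.null(config)) config <- default_application_config()
  pp <- config_to_physical(config)
  pb <- config$phase
  for (f in c("Davg_um2s", "tc_s"))
    if (!(is.numeric(pb[[f]]) && length(pb[[f]]) == 1L))
      stop("config error: missing or non-numeric phase input: ", f)
  Z_G <- if (is.null(pb$Z_G)) 1 else pb$Z_G
  chol <- config$cholesterol_viscosity_factor
  if (is.null(chol)) chol <- 1.2

  D <- einstein_diffusivity(pp)
  phase <- infer_liquid_phase(Davg = pb$Davg_um2s, D = D, Z_G = Z_G,
                              tc = pb$tc_s)
  pp_chol <- pp
  pp_chol$viscosity_multiplier <- pp$viscosity_multiplier * chol
  D_chol <- einstein_diffusivity(pp_chol)

  curves <- lapply(curve_times, function(t) {
    observed_pdf(observed_grid(phase, t, grid_n), t, phase, as_pdf = TRUE)
  })
  names(curves) <- sprintf("t=%gs", curve_times)

  structure(list(params = pp, phase = phase, D = D,
                 D_cholesterol = D_chol, DeffL = phase$DeffL,
                 Z_L = phase$Z_L, Davg = phase$Davg, tc = phase$tc,
                 gaussianity_time_s = gaussianity_time(phase, threshold),
                 threshold = threshold, curves = curves),
            class = "bnyg_report")
}

#' @export
print.bnyg_report <- function(x, ...) {
  # two significant figures in display only; the list fields keep full
  # precision
  s2 <- function(v) signif(v, 2)
  cat("Two-regime phase-separation model -- derived quantities\n")
  cat(sprintf("  bare diffusivity D            : %g um^2/s\n", s2(x$D)))
  cat(sprintf("  cholesterol control D         : %g um^2/s\n",
              s2(x$D_cholesterol)))
  cat(sprintf("  measured average Davg         : %g um^2/s\n", s2(x$Davg)))
  cat(sprintf("  liquid-phase DeffL            : %g um^2/s\n", s2(x$DeffL)))
  cat(sprintf("  liquid compressibility Z_L    : %g\n", s2(x$Z_L)))
  cat(sprintf("  critical time tc              : %g s\n", x$tc))
  cat(sprintf("  Gaussianization time after tc : %g s (kurtosis < %g)\n",
              s2(x$gaussianity_time_s), x$threshold))
  cat(sprintf("  model curves at               : %s\n",
              paste(names(x$curves), collapse = ", ")))
  invisible(x)
}

#' Serialise a report's scalars to JSON
#'
#' @param report A [reproduce_application()] result.
#' @param path Optional file to write; `NULL` returns the JSON string.
#' @param curve_dir Optional directory; when given, each model curve is
#'   written there as a CSV (`x_um, density`) and the file paths are
#'   included in the JSON.
#' @return The JSON string, invisibly when written to file.
#' @export
report_to_json <- function(report, path = NULL, curve_dir = NULL) {
  stopifnot(inherits(report, "bnyg_report"))
  out <- report[c("D", "D_cholesterol", "DeffL", "Z_L", "Davg", "tc",
                  "gaussianity_time_s", "threshold")]
  if (!is.null(curve_dir)) {
    dir.create(curve_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (nm in names(report$curves)) {
      cu <- report$curves[[nm]]
      f <- file.path(curve_dir,
                     paste0("curve_", gsub("[^0-9a-zA-Z.]", "_", nm),
                            ".csv"))
      utils::write.csv(data.frame(x_um = cu$grid, density = cu$density),
                       f, row.names = FALSE)
      files <- c(files, f)
    }
    out$curve_files <- files
  }
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Tabulate a model curve on figure-style axes
#'
#' @param pdf A [displacement_pdf()].
#' @param diameter Particle diameter in um (displacements are often
#'   plotted in diameter units).
#' @param presentation `"normalized"` keeps the unit-mass density;
#'   `"rescaled_unnormalized"` divides by the peak value so the curve's
#'   log10 starts at 0, the un-normalised presentation used in
#'   figure-style log plots.
#' @return data.frame with `x_um`, `x_over_d`, `density`,
#'   `log10_density`.
#' @export
curve_table <- function(pdf, diameter = 0.1,
                        presentation = c("normalized",
                                         "rescaled_unnormalized")) {
  stopifnot(inherits(pdf, "displacement_pdf"),
            is.numeric(diameter), length(diameter) == 1L, diameter > 0)
  presentation <- match.arg(presentation)
  dens <- pdf$density
  if (presentation == "rescaled_unnormalized") dens <- dens / max(dens)
  data.frame(x_um = pdf$grid, x_over_d = pdf$grid / diameter,
             density = dens,
             log10_density = ifelse(dens > 0, log10(dens), -Inf))
}

#' Displacement-histogram table
#'
#' Validates a user-supplied displacement histogram: displacements in
#' units of the particle diameter, log10 of the (possibly un-normalised)
#' probability density, one observation time per table.
#'
#' @param x Either a data.frame with columns `x_over_d`, `log10_density`,
#'   `time_s`, or a path to a CSV file with that header.
#' @param diameter Particle diameter in um.
#' @return Object of class `histogram_table` (a data.frame with the three
#'   columns, attribute `diameter`).
#' @export
histogram_table <- function(x, diameter = 0.1) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("histogram file not found: ", x)
    x <- utils::read.csv(x)
  }
  stopifnot(is.data.frame(x), is.numeric(diameter), diameter > 0)
  need <- c("x_over_d", "log10_density", "time_s")
  if (!all(need %in% names(x)))
    stop("histogram table needs columns: ", paste(need, collapse = ", "))
  if (!all(is.finite(x$x_over_d)) || !all(is.finite(x$log10_density)))
    stop("histogram table contains non-finite values")
  if (length(unique(x$time_s)) != 1L || any(x$time_s <= 0))
    stop("histogram table must carry a single positive time_s")
  structure(x[need], class = c("histogram_table", "data.frame"),
            diameter = diameter)
}

#' Fixed-intercept regression error between a model curve and data
#'
#' Implements the percentage-error score used for figure-level comparison:
#' fix the lowest-order parameter (the log10 intercept at zero
#' displacement) to the model's value, fit the highest-order coefficient
#' by least squares on both the model curve and the data, and report
#' `100 * |coef_data - coef_model| / |coef_model|`.
#'
#' On the Laplace branch (`regime_label == "gas"`) the log10 density is
#' linear in `|x|` and the coefficient is the slope; on the transition /
#' Gaussian branch it is the quadratic coefficient of `x^2`.  Fits are
#' performed in diameter units, matching the data table's axes.
#'
#' @param model_curve A [displacement_pdf()]; must share the data's time
#'   stamp.
#' @param data A [histogram_table()] (or data.frame/CSV path coercible to
#'   one).
#' @param diameter Particle diameter in um (used if `data` is not already
#'   a `histogram_table`).
#' @param align_intercept Logical; un-normalised data carry an arbitrary
#'   vertical offset in log10 density.  `TRUE` estimates that offset from
#'   an unconstrained fit and removes it before the fixed-intercept fit.
#'   The default `FALSE` assumes the data share the model's
#'   normalisation; only then is the returned error exactly
#'   scale-equivariant.
#' @return List with `percent_error`, `coef_model`, `coef_data`,
#'   `branch` (`"linear"` or `"quadratic"`), `intercept`.
#' @export
slope_error <- function(model_curve, data, diameter = 0.1,
                        align_intercept = FALSE) {
  stopifnot(inherits(model_curve, "displacement_pdf"))
  if (!inherits(data, "histogram_table"))
    data <- histogram_table(data, diameter)
  d <- attr(data, "diameter")
  if (nrow(data) < 3L) stop("need at least 3 data points")
  if (abs(data$time_s[1] - model_curve$time) > 1e-9)
    stop(sprintf("time mismatch: data at %g s, model at %g s",
                 data$time_s[1], model_curve$time))
  branch <- if (model_curve$regime_label == "gas") "linear" else
    "quadratic"

  # model log10 density at the data abscissae and at zero, by
  # interpolation on the model grid (log-space: both branches are
  # polynomial there)
  logmod <- function(x_um) {
    stats::approx(model_curve$grid, log10(model_curve$density),
                  xout = x_um, rule = 2)$y
  }
  x_um <- data$x_over_d * d
  a0 <- logmod(0)

  u_data <- if (branch == "linear") abs(data$x_over_d) else
    data$x_over_d^2
  if (all(u_data == 0)) stop("singular design: all abscissae are zero")
  y_data <- data$log10_density
  if (isTRUE(align_intercept)) {
    cf <- stats::coef(stats::lm(y_data ~ u_data))
    y_data <- y_data - (unname(cf[1]) - a0)
  }

  fixed_fit <- function(u, y) sum(u * (y - a0)) / sum(u^2)
  u_mod <- u_data
  y_mod <- logmod(x_um)
  coef_model <- fixed_fit(u_mod, y_mod)
  coef_data <- fixed_fit(u_data, y_data)
  if (!is.finite(coef_model) || coef_model == 0)
    stop("singular design: model coefficient is zero")
  list(percent_error = 100 * abs(coef_data - coef_model) /
         abs(coef_model),
       coef_model = coef_model, coef_data = coef_data,
       branch = branch, intercept = a0)
}
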