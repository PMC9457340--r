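test_that("reproduce_application recovers the worked scalar chain", {
  rep <- reproduce_application()
  expect_equal(signif(rep$D, 2), 0.014)
  expect_equal(signif(rep$DeffL, 2), 0.79)
  expect_equal(rep$Z_L, 0.13, tolerance = 0.045)
  expect_equal(signif(rep$D_cholesterol, 2), 0.012)
  # internal consistency of the inversion
  expect_equal(rep$DeffL, 2 * rep$Davg - rep$D)
  expect_equal(rep$Z_L, sqrt(rep$D / rep$DeffL))
  expect_lte(rep$gaussianity_time_s, 2)
  expect_named(rep$curves, c("t=0.06s", "t=0.6s", "t=3s", "t=5.8s"))
  labs <- vapply(rep$curves, `[[`, "", "regime_label")
  expect_identical(unname(labs), c("gas", "gas", "gas", "transition"))
  for (cu in rep$curves)
    expect_lt(abs(trapint(cu$grid, cu$density) - 1), 1e-6)
  expect_error(reproduce_application(list(physical = list(), phase = list())),
               "config error")
})

test_that("report JSON and curve CSVs round-trip", {
  rep <- reproduce_application(curve_times = c(3, 5.8))
  dir <- withr::local_tempdir()
  out <- file.path(dir, "report.json")
  report_to_json(rep, path = out, curve_dir = file.path(dir, "curves"))
  js <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(js$D, rep$D, tolerance = 1e-12)
  expect_equal(js$gaussianity_time_s, rep$gaussianity_time_s,
               tolerance = 1e-12)
  expect_length(js$curve_files, 2)
  cu <- read.csv(js$curve_files[1])
  expect_named(cu, c("x_um", "density"))
})

test_that("config files in YAML and JSON are read with defaults filled in", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cfg.yaml")
  writeLines(c("physical:", "  viscosity_multiplier: 120",
               "phase:", "  Davg_um2s: 0.5"), yml)
  cfg <- read_config(yml)
  expect_equal(cfg$physical$viscosity_multiplier, 120)
  expect_equal(cfg$physical$temperature_C, 22)     # default preserved
  expect_equal(cfg$phase$Davg_um2s, 0.5)
  jsn <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(phase = list(tc_s = 2)), jsn,
                       auto_unbox = TRUE)
  expect_equal(read_config(jsn)$phase$tc_s, 2)
  expect_error(read_config(file.path(dir, "nope.yaml")), "not found")
})

test_that("curve_table emits figure-style axes", {
  rep <- reproduce_application(curve_times = 0.06)
  tab <- curve_table(rep$curves[[1]], diameter = 0.1)
  expect_named(tab, c("x_um", "x_over_d", "density", "log10_density"))
  expect_equal(tab$x_over_d, tab$x_um / 0.1)
  un <- curve_table(rep$curves[[1]], diameter = 0.1,
                    presentation = "rescaled_unnormalized")
  expect_equal(max(un$density), 1)
  expect_equal(max(un$log10_density), 0)
})

test_that("slope_error is zero on self-consistent data and scale-equivariant", {
  ph <- bead_phase()
  d <- 0.1
  for (t in c(0.06, 5.8)) {
    curve <- observed_pdf(observed_grid(ph, t), t, ph, as_pdf = TRUE)
    half <- max(curve$grid)
    xd <- seq(0.2, half / d * 0.3, length.out = 12)
    y <- approx(curve$grid, log10(curve$density), xout = xd * d)$y
    data <- data.frame(x_over_d = xd, log10_density = y, time_s = t)
    res0 <- slope_error(curve, data, diameter = d)
    expect_lt(res0$percent_error, 1e-8)
    expect_identical(res0$branch,
                     if (t <= ph$tc) "linear" else "quadratic")
    # scaling the coefficient by (1 + e) returns 100 e
    a0 <- res0$intercept
    for (e in c(0.02, -0.05, 0.1)) {
      data2 <- data
      data2$log10_density <- a0 + (1 + e) * (y - a0)
      expect_equal(slope_error(curve, data2, diameter = d)$percent_error,
                   100 * abs(e), tolerance = 1e-6)
    }
  }
})

test_that("slope_error tolerates a vertical offset (un-normalised data)", {
  ph <- bead_phase()
  curve <- observed_pdf(observed_grid(ph, 0.6), 0.6, ph, as_pdf = TRUE)
  xd <- seq(1, 15, length.out = 10)
  y <- approx(curve$grid, log10(curve$density), xout = xd * 0.1)$y
  data <- data.frame(x_over_d = xd, log10_density = y + 2.7, time_s = 0.6)
  # on the Laplace branch log10 density is exactly linear, so the
  # unconstrained alignment recovers the offset exactly
  expect_lt(slope_error(curve, data, diameter = 0.1,
                        align_intercept = TRUE)$percent_error, 1e-6)
  # without alignment the offset corrupts the coefficient
  expect_gt(slope_error(curve, data, diameter = 0.1)$percent_error, 1)
})

test_that("slope_error and histogram_table reject malformed input", {
  ph <- bead_phase()
  curve <- observed_pdf(observed_grid(ph, 3), 3, ph, as_pdf = TRUE)
  good <- data.frame(x_over_d = 1:5, log10_density = -(1:5) / 2,
                     time_s = 3)
  expect_error(slope_error(curve, good[1:2, ]), "3 data points")
  bad_t <- good; bad_t$time_s <- 2.5
  expect_error(slope_error(curve, bad_t), "time mismatch")
  expect_error(histogram_table(good[, 1:2]), "columns")
  zero <- data.frame(x_over_d = numeric(3), log10_density = -1:1,
                     time_s = 3)
  expect_error(slope_error(curve, zero), "singular")
})

test_that("CLI subcommands run end to end", {
  dir <- withr::local_tempdir()
  out <- capture.output(bnyg_cli(c("infer", "--json")))
  js <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_equal(signif(js$D_um2s, 2), 0.014)
  expect_equal(js$Z_L, 0.1354, tolerance = 1e-3)

  gt <- capture.output(bnyg_cli("gauss-time"))
  expect_lte(as.numeric(gt[length(gt)]), 2)

  pdf_csv <- file.path(dir, "pdf.csv")
  bnyg_cli(c("pdf", "--time", "3", "--grid", "3,101", "--out", pdf_csv))
  tab <- read.csv(pdf_csv)
  expect_named(tab, c("x_um", "x_over_d", "density", "log10_density"))
  expect_equal(nrow(tab), 101)

  mech_csv <- file.path(dir, "mech.csv")
  bnyg_cli(c("mechanism", "--grid", "1,50,20", "--out", mech_csv))
  expect_equal(nrow(read.csv(mech_csv)), 20)

  traj <- file.path(dir, "traj.csv")
  suppressMessages(bnyg_cli(c("simulate", "--n", "200", "--dt", "0.01",
                              "--tmax", "2", "--stride", "100",
                              "--seed", "4", "--out", traj)))
  long <- read.csv(traj)
  expect_named(long, c("path_id", "regime", "t", "x_um"))
  st_out <- capture.output(bnyg_cli(c("stats", "--in", traj,
                                      "--times", "1,2")))
  expect_match(st_out[1], "time")

  hist_csv <- file.path(dir, "hist.csv")
  ph <- bead_phase()
  curve <- observed_pdf(observed_grid(ph, 0.06), 0.06, ph, as_pdf = TRUE)
  xd <- seq(0.5, 8, length.out = 8)
  write.csv(data.frame(
    x_over_d = xd,
    log10_density = approx(curve$grid, log10(curve$density),
                           xout = xd * 0.1)$y,
    time_s = 0.06), hist_csv, row.names = FALSE)
  cmp <- capture.output(bnyg_cli(c("compare", "--model-time", "0.06",
                                   "--data", hist_csv)))
  expect_lt(jsonlite::fromJSON(paste(cmp, collapse = "\n"))$percent_error,
            0.01)
  expect_output(bnyg_cli(character(0)), "usage")
})
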