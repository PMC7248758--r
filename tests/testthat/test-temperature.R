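test_that("baseline correction subtracts the two-edge line exactly", {
  wl <- seq(1300, 1600, 0.5)
  lin <- spectral_dataset(wl, rbind(0.2 + 0.001 * wl, rep(0.7, 601)))
  bc <- baseline_correct(lin)
  expect_lt(max(abs(bc$absorbance)), 1e-12)
  # Gaussian band on a sloped line -> the pure Gaussian
  g <- exp(-0.5 * ((wl - 1450) / 20)^2)
  ds <- spectral_dataset(wl, matrix(g + 0.3 - 0.002 * (wl - 1300), 1))
  line <- 0.3 - 0.002 * (wl - 1300) +
    (g[601] - g[1]) * (wl - 1300) / 300 + g[1]
  expect_lt(max(abs(baseline_correct(ds)$absorbance[1, ] -
                      (g + 0.3 - 0.002 * (wl - 1300) - line))), 1e-12)
  expect_equal(baseline_correct(ds)$absorbance[1, c(1, 601)], c(0, 0))
  short <- spectral_dataset(seq(1310, 1590, 0.5),
                            matrix(1, 1, 561))
  expect_error(baseline_correct(short), "empty intersection|range")
})

test_that("relative areas match the closed-form triangle oracle", {
  wl <- seq(1300, 1600, 0.5)
  tri <- ifelse(wl <= 1450, (wl - 1300) / 150, (1600 - wl) / 150)
  ds <- spectral_dataset(wl, matrix(tri, 1))
  ra <- relative_areas(ds)
  expect_equal(ra$total_auc, 150)
  # C05 = [1406, 1418]: integral of (x-1300)/150 = (118^2-106^2)/300
  expect_equal(unname(ra$rel_area[1, "C05"]), (118^2 - 106^2) / 300 / 150,
               tolerance = 1e-12)
  expect_equal(unname(ra$rel_area[1, "C05"]), 0.0597, tolerance = 1e-3)
  # positive scaling leaves every relative area unchanged
  ra2 <- relative_areas(spectral_dataset(wl, matrix(7.3 * tri, 1)))
  expect_equal(ra2$rel_area, ra$rel_area, tolerance = 1e-14)
  # zero signal inside C01's range
  z <- tri; z[wl >= 1330 & wl <= 1352] <- 0
  expect_equal(unname(relative_areas(spectral_dataset(wl, matrix(z, 1))
                                     )$rel_area[1, "C01"]), 0)
  expect_error(relative_areas(spectral_dataset(wl, matrix(-tri, 1))),
               "degenerate-spectrum")
})

test_that("reference curves reproduce polynomial relative-area trends", {
  # bands with negligible tails at the window edges: total corrected area is
  # constant, so rel_area is exactly linear in T and the local quadratic
  # smoother must reproduce the line
  narrow <- nir_water_model(bands = data.frame(
    center_nm = c(1412, 1462), sigma_nm = c(12, 12),
    amplitude = c(0.55, 0.75), dA_dC = c(0.004, -0.004)),
    noise_sd = 0, scatter = c(mult_sd = 0, add_sd = 0))
  refl <- simulate_temperature_series(narrow, seed = 1)
  cl <- build_reference_curves(refl)
  avgl <- average_consecutive_scans(subset_wavelengths(refl, 1300, 1600),
                                    "temperature_C")
  rawl <- relative_areas(baseline_correct(avgl))$rel_area
  atl <- match(avgl$meta$temperature_C, round(cl$T_grid, 6))
  expect_lt(max(abs(cl$curves[atl, ] - rawl)), 1e-6)
  # four-band model: rel_area(T) is a smooth ratio, reproduced to ~curvature
  ref <- ref_noiseless()
  curves <- build_reference_curves(ref)
  expect_equal(range(curves$T_grid), c(20, 70))
  avg <- average_consecutive_scans(subset_wavelengths(ref, 1300, 1600),
                                   "temperature_C")
  raw <- relative_areas(baseline_correct(avg))$rel_area
  at <- match(avg$meta$temperature_C, round(curves$T_grid, 6))
  expect_lt(max(abs(curves$curves[at, ] - raw)), 1e-5)
  # smoothing beats the noise: MAE of curve vs truth < noise SD of raw points
  m <- nir_water_model("four_band")
  refn <- simulate_temperature_series(m, seed = 21)
  curvn <- build_reference_curves(refn)
  noise <- sd((relative_areas(baseline_correct(
    average_consecutive_scans(subset_wavelengths(refn, 1300, 1600),
                              "temperature_C")))$rel_area - raw))
  mae <- mean(abs(curvn$curves[at, ] - raw))
  expect_lt(mae, noise)
  few <- aquagrams:::subset_rows(ref, ref$meta$temperature_C <= 26)
  expect_error(build_reference_curves(few), "fit error")
})

test_that("local calibration inverts exactly on linear curves", {
  ref <- ref_noiseless()
  curves <- build_reference_curves(ref)
  cal <- local_calibration(curves, 28)
  expect_equal(cal$window, c(26, 30))
  # alpha/beta reproduce the least-squares line of the curve in the window
  inw <- curves$T_grid >= 26 & curves$T_grid <= 30
  for (j in c(1, 5, 9)) {
    f <- lm(curves$curves[inw, j] ~ curves$T_grid[inw])
    expect_equal(unname(cal$alpha[j]), unname(coef(f)[1]), tolerance = 1e-9)
    expect_equal(unname(cal$beta[j]), unname(coef(f)[2]), tolerance = 1e-9)
  }
  # fixed point: the curve value at experiment_T maps back to experiment_T
  at28 <- curves$curves[match(28, round(curves$T_grid, 6)), ]
  expect_equal(unname(temperature_equivalent(cal, at28)), rep(28, 12),
               tolerance = 0.05)
  # algebraic inversion oracle at a known T* inside the window
  at29.5 <- curves$curves[match(29.5, round(curves$T_grid, 6)), ]
  expect_equal(unname(temperature_equivalent(cal, at29.5)), rep(29.5, 12),
               tolerance = 0.05)
  expect_error(local_calibration(curves, 75), "range error")
})

test_that("ill-conditioned coordinates are suppressed, not fabricated", {
  # two-band model: C01/C02/C12 see only far Gaussian tails -> |beta| ~ 0
  ref <- simulate_temperature_series(noiseless(nir_water_model()), seed = 31)
  cal <- temperature_calibration(ref, 28)
  expect_false(any(cal$conditioned[c("C01", "C02", "C12")]))
  expect_true(all(cal$conditioned[c("C05", "C08", "C09")]))
  expect_error(temperature_equivalent(cal, 0.01, coordinate = "C01"),
               "conditioning error")
  v <- temperature_equivalent(cal, rep(0.04, 12))
  expect_true(all(is.na(v[c("C01", "C02", "C12")])))
  # constant curve => beta = 0 => flagged
  flat <- build_reference_curves(ref)
  flat$curves[, "C05"] <- 0.05
  calf <- local_calibration(flat, 28)
  expect_false(calf$conditioned[["C05"]])
})

test_that("temperature aquagram recovers known temperatures end to end", {
  m <- nir_water_model("four_band")
  ref <- ref_noiseless()
  # self-consistency: the reference's own 28 C step maps to ~28 everywhere
  own <- simulate_temperature_series(noiseless(m), temps = 28, n_scans = 3)
  aq <- temp_aquagram(own, ref, experiment_T = 28, n_boot = 100, seed = 1)
  expect_lt(max(abs(coef(aq) - 28), na.rm = TRUE), 0.2)
  # noisy groups inside the window recovered within 0.3 C
  expg <- simulate_temperature_series(m, temps = rep(c(27, 29), each = 40),
                                      n_scans = 3, seed = 41)
  expg$meta$group_label <- sprintf("G%g", expg$meta$temperature_C)
  aq2 <- temp_aquagram(expg, ref, experiment_T = 28, n_boot = 100, seed = 2)
  err <- abs(sweep(coef(aq2), 1, c(27, 29)))
  expect_lt(max(err, na.rm = TRUE), 0.3)
  expect_aquagram_shape(aq2, 2, "absolute")
})

test_that("group values do not depend on unrelated groups", {
  m <- nir_water_model("four_band")
  ref <- ref_noiseless()
  ds <- simulate_temperature_series(m, temps = c(24, 28, 32), n_scans = 3,
                                    seed = 51)
  both <- temp_aquagram(ds, ref, n_boot = 100, seed = 7)
  alone <- temp_aquagram(aquagrams:::subset_rows(ds, ds$meta$temperature_C == 28),
                         ref, n_boot = 100, seed = 7)
  expect_equal(coef(both)["T28", ], coef(alone)["T28", ], tolerance = 1e-10)
})

test_that("scaling all experimental spectra leaves values unchanged", {
  ref <- ref_noiseless()
  ds <- simulate_temperature_series(nir_water_model("four_band"),
                                    temps = c(27, 29), n_scans = 3,
                                    seed = 61)
  scaled <- spectral_dataset(ds$wavelengths, 3.7 * ds$absorbance, ds$meta)
  a <- temp_aquagram(ds, ref, experiment_T = 28, n_boot = 100, seed = 3)
  b <- temp_aquagram(scaled, ref, experiment_T = 28, n_boot = 100, seed = 3)
  expect_equal(coef(a), coef(b), tolerance = 1e-9)
})

test_that("confidence intervals bracket values and shrink with group size", {
  m <- nir_water_model("four_band")
  ref <- ref_noiseless()
  small <- simulate_temperature_series(m, temps = rep(28, 1), n_scans = 3,
                                       seed = 71)
  big <- simulate_temperature_series(m, temps = rep(28, 10), n_scans = 3,
                                     seed = 72)
  big$meta$group_label <- "T28"
  aqs <- temp_aquagram(small, ref, experiment_T = 28, n_boot = 400, seed = 4)
  aqb <- temp_aquagram(big, ref, experiment_T = 28, n_boot = 400, seed = 4)
  ws <- as.data.frame(aqs); wb <- as.data.frame(aqb)
  expect_true(all(ws$lcl95 <= ws$value & ws$value <= ws$ucl95, na.rm = TRUE))
  expect_lt(mean(wb$ucl95 - wb$lcl95, na.rm = TRUE),
            mean(ws$ucl95 - ws$lcl95, na.rm = TRUE))
})

test_that("delta reporting compares groups to the control through the chain", {
  m4 <- nir_water_model("four_band")
  sol <- simulate_solute_series(noiseless(m4),
                                concentrations_mM = c(100, 1000),
                                n_reps = 2, n_scans = 3, n_controls = 4,
                                seed = 81)
  aq <- temp_aquagram(sol, ref_noiseless(), experiment_T = 28,
                      control_group = "MilliQ", n_boot = 150, seed = 5)
  df <- as.data.frame(aq)
  expect_setequal(unique(df$mode), c("absolute", "delta"))
  d <- df[df$mode == "delta", ]
  a <- df[df$mode == "absolute", ]
  ctrl <- a[a$group == "MilliQ", ]
  g100 <- a[a$group == "100mM", ]
  expect_equal(d$value[d$group == "100mM"], g100$value - ctrl$value,
               tolerance = 1e-12)
  expect_error(temp_aquagram(sol, ref_noiseless(), control_group = "nope",
                             experiment_T = 28, n_boot = 100),
               "not among groups")
})
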