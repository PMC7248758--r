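test_that("construction validates the dataset invariants", {
  wl <- seq(1300, 1600, 0.5)
  expect_s3_class(spectral_dataset(wl, matrix(1, 2, length(wl)),
                                   declared_step = 0.5),
                  "spectral_dataset")
  expect_error(spectral_dataset(c(1300, 1300.5, 1300.5), matrix(1, 1, 3)),
               "strictly increasing")
  expect_error(spectral_dataset(wl, matrix(c(NA, rep(1, length(wl) - 1)), 1)),
               "non-finite")
  expect_error(spectral_dataset(wl, matrix(1, 2, length(wl)),
                                meta = data.frame(x = 1)),
               "rows")
  expect_error(spectral_dataset(c(1300, 1300.5, 1301.1), matrix(1, 1, 3),
                                declared_step = 0.5),
               "declared step")
})

test_that("wide CSV round-trips through write/read to 1e-12", {
  ds <- toy_dataset()
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra(ds, f)
  back <- read_spectra(f, declared_step = 0.5)
  expect_identical(back$wavelengths, ds$wavelengths)
  expect_lt(max(abs(back$absorbance - ds$absorbance)), 1e-12)
  expect_identical(back$meta$group_label, ds$meta$group_label)
})

test_that("long and wide dialects parse to the same dataset", {
  ds <- toy_dataset(2, wl = seq(1300, 1600, 0.5))
  fw <- withr::local_tempfile(fileext = ".csv")
  fl <- withr::local_tempfile(fileext = ".csv")
  write_spectra(ds, fw, "wide")
  write_spectra(ds, fl, "long")
  w <- read_spectra(fw, "wide")
  l <- read_spectra(fl, "long")
  expect_equal(l$wavelengths, w$wavelengths)
  expect_lt(max(abs(l$absorbance - w$absorbance)), 1e-12)
  expect_identical(l$meta$sample_id, w$meta$sample_id)
  expect_equal(ncol(w$absorbance), 601)
})

test_that("read errors are specific: header, parse, monotonicity", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group_label", "s1,a"), f)
  expect_error(read_spectra(f), "no wavelength columns")
  writeLines(c("sample_id,1300,1300.5", "s1,0.1,oops"), f)
  expect_error(read_spectra(f), "non-numeric absorbance")
  writeLines(c("sample_id,1300,1300", "s1,0.1,0.2"), f)
  expect_error(read_spectra(f), "duplicated wavelength")
  expect_error(read_spectra("/nonexistent/file.csv"), "not found")
})

test_that("subset_wavelengths keeps inclusive bounds and is idempotent", {
  ds <- spectral_dataset(seq(400, 2500, 0.5),
                         matrix(runif(2 * 4201), nrow = 2))
  s <- subset_wavelengths(ds, 1300, 1600)
  expect_equal(length(s$wavelengths), 601)
  expect_equal(range(s$wavelengths), c(1300, 1600))
  s2 <- subset_wavelengths(s, 1300, 1600)
  expect_identical(s2$absorbance, s$absorbance)
  one <- subset_wavelengths(ds, 1450, 1450)
  expect_equal(one$wavelengths, 1450)
  expect_error(subset_wavelengths(s, 1601, 1700), "empty intersection")
})

test_that("scan averaging collapses groups and records n", {
  m <- nir_water_model()
  ds <- simulate_temperature_series(m, seed = 1)   # 26 temps x 3 scans
  avg <- average_consecutive_scans(ds, by = "temperature_C")
  expect_equal(nrow(avg$absorbance), 26)
  expect_true(all(avg$meta$n_scans == 3))
  expect_false("scan_index" %in% names(avg$meta))
  # two-point mean and idempotence on identical spectra
  wl <- seq(1300, 1600, 0.5)
  d2 <- spectral_dataset(wl, rbind(rep(0.2, 601), rep(0.4, 601)),
                         data.frame(sample_id = c("x", "x")))
  expect_equal(unique(average_consecutive_scans(d2, "sample_id")$absorbance[1, ]),
               0.3)
  d3 <- spectral_dataset(wl, rbind(rep(0.2, 601), rep(0.2, 601)),
                         data.frame(sample_id = c("x", "x")))
  expect_equal(unique(average_consecutive_scans(d3, "sample_id")$absorbance[1, ]),
               0.2)
})

test_that("averaging commutes with wavelength subsetting", {
  ds <- simulate_temperature_series(nir_water_model(), temps = c(20, 30),
                                    grid = c(1290, 1610, 0.5), seed = 3)
  a <- subset_wavelengths(average_consecutive_scans(ds, "temperature_C"),
                          1300, 1600)
  b <- average_consecutive_scans(subset_wavelengths(ds, 1300, 1600),
                                 "temperature_C")
  expect_equal(a$absorbance, b$absorbance, tolerance = 1e-14)
})
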