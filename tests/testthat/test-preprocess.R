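test_that("msc removes affine distortions of a common shape", {
  wl <- seq(1300, 1600, 0.5)
  shape <- 0.2 + exp(-0.5 * ((wl - 1450) / 40)^2)
  # identity and exact affine case
  ds2 <- spectral_dataset(wl, rbind(shape, 2 * shape + 5))
  out <- msc(ds2, reference = shape)
  cf <- attr(out, "msc_coefficients")
  expect_equal(cf$a, c(1, 2))
  expect_equal(cf$b, c(0, 5))
  expect_lt(max(abs(out$absorbance[2, ] - shape)), 1e-10)
  # 10 random distortions against the explicit least-squares oracle
  set.seed(42)
  a <- runif(10, 0.5, 2); b <- runif(10, -1, 1)
  ds10 <- spectral_dataset(wl, a %o% shape + b)
  corrected <- msc(ds10, reference = shape)$absorbance
  for (i in 1:10) {
    fit <- lm(ds10$absorbance[i, ] ~ shape)       # independent oracle
    oracle <- (ds10$absorbance[i, ] - coef(fit)[1]) / coef(fit)[2]
    expect_lt(max(abs(corrected[i, ] - oracle)), 1e-10)
    expect_lt(max(abs(corrected[i, ] - shape)), 1e-10)
  }
  expect_error(msc(ds2, reference = rep(1, length(wl))), "degenerate-fit")
  expect_error(msc(spectral_dataset(wl, matrix(shape, 1))), ">= 2 spectra")
})

test_that("msc with a fixed reference is invariant to affine distortion", {
  ds <- toy_dataset(4)
  ref <- colMeans(ds$absorbance)
  set.seed(7)
  a <- runif(4, 0.8, 1.2); b <- runif(4, -0.2, 0.2)
  dist <- spectral_dataset(ds$wavelengths, a * ds$absorbance + b, ds$meta)
  expect_lt(max(abs(msc(dist, ref)$absorbance - msc(ds, ref)$absorbance)),
            1e-10)
})

test_that("snv standardizes each spectrum and is idempotent", {
  ds <- toy_dataset(3)
  out <- snv(ds)
  expect_equal(unname(rowMeans(out$absorbance)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(out$absorbance, 1, sd)), rep(1, 3),
               tolerance = 1e-12)
  expect_equal(snv(out)$absorbance, out$absorbance, tolerance = 1e-12)
  s3 <- spectral_dataset(c(1, 2, 3), matrix(c(1, 2, 3), 1))
  expect_equal(as.vector(snv(s3)$absorbance), c(-1, 0, 1))
  expect_error(snv(spectral_dataset(1:3, matrix(1, 1, 3))), "degenerate")
})

test_that("sg derivative reproduces polynomials and locates band minima", {
  wl <- seq(1300, 1600, 0.5)
  quad <- spectral_dataset(wl, matrix(3e-4 * wl^2 - 0.8 * wl + 10, 1))
  d2 <- sg_derivative(quad, 21, 2, 2)
  interior <- setdiff(seq_along(wl), attr(d2, "sg_edge_region"))
  expect_equal(unique(round(d2$absorbance[1, interior], 10)), 6e-4)
  # Gaussian band: analytic 2nd derivative minimum at the center
  g <- spectral_dataset(wl, matrix(exp(-0.5 * ((wl - 1412) / 16)^2), 1))
  d2g <- sg_derivative(g, 21, 2, 2)
  expect_lt(abs(wl[which.min(d2g$absorbance[1, ])] - 1412), 0.51)
  expect_error(sg_derivative(quad, 20, 2, 2), "parameter error")
  expect_error(sg_derivative(quad, 21, 1, 2), "parameter error")
})

test_that("sg derivative is linear and resolves the two water bands", {
  wl <- seq(1300, 1600, 0.5)
  x <- exp(-0.5 * ((wl - 1412) / 16)^2)
  y <- 0.7 * exp(-0.5 * ((wl - 1500) / 25)^2)
  dx <- sg_derivative(spectral_dataset(wl, matrix(x, 1)))$absorbance
  dy <- sg_derivative(spectral_dataset(wl, matrix(y, 1)))$absorbance
  dxy <- sg_derivative(spectral_dataset(wl, matrix(x + y, 1)))$absorbance
  expect_equal(dxy, dx + dy, tolerance = 1e-10)
  # noiseless two-band water model: minima at the configured band centers
  m <- noiseless(nir_water_model())
  ds <- simulate_temperature_series(m, temps = 45, n_scans = 1)
  d2 <- sg_derivative(ds)$absorbance[1, ]
  lo <- wl >= 1390 & wl <= 1435
  hi <- wl >= 1435 & wl <= 1490
  expect_lt(abs(wl[lo][which.min(d2[lo])] - 1412), 2)
  expect_lt(abs(wl[hi][which.min(d2[hi])] - 1462), 2)
})

test_that("pca explained variance behaves on rank-1 and noisy data", {
  wl <- seq(1300, 1600, 0.5)
  shape <- exp(-0.5 * ((wl - 1450) / 40)^2)
  rank1 <- spectral_dataset(wl, seq(0.5, 2, length.out = 6) %o% shape)
  p <- pca_explained(rank1, 2)
  expect_equal(p$explained[1], 1, tolerance = 1e-10)
  set.seed(3)
  noisy <- spectral_dataset(wl, rank1$absorbance +
                                matrix(rnorm(6 * 601, 0, 1e-3), 6))
  p2 <- pca_explained(noisy, 3)
  expect_gt(p2$explained[1], 0.99)
  expect_true(all(diff(p2$explained) <= 1e-12))
  expect_lte(sum(p2$explained), 1)
  # eigendecomposition of the covariance as the independent oracle
  ev <- eigen(cov(noisy$absorbance), symmetric = TRUE,
              only.values = TRUE)$values
  expect_equal(p2$explained, (ev / sum(ev))[1:3], tolerance = 1e-8)
  # permutation invariance of row order
  perm <- aquagrams:::subset_rows(noisy, c(4, 2, 6, 1, 3, 5))
  expect_equal(pca_explained(perm, 3)$explained, p2$explained,
               tolerance = 1e-10)
  expect_error(pca_explained(noisy, 6), "parameter error")
})
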