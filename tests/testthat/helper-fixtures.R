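# Small fixtures built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny dataset: ns spectra on a short grid, distinct smooth shapes
toy_dataset <- function(ns = 3, wl = seq(1300, 1600, 0.5)) {
  A <- t(vapply(seq_len(ns), function(i)
    0.1 * i + (0.5 + 0.1 * i) * exp(-0.5 * ((wl - 1400 - 10 * i) / 30)^2),
    numeric(length(wl))))
  spectral_dataset(wl, A, data.frame(
    sample_id = paste0("s", seq_len(ns)),
    group_label = paste0("g", seq_len(ns))))
}

# two non-affinely-related spectra, one group each (classic closed form)
two_group_fixture <- function() {
  wl <- seq(1300, 1600, 0.5)
  A <- rbind(0.3 + exp(-0.5 * ((wl - 1412) / 16)^2),
             0.3 + exp(-0.5 * ((wl - 1462) / 20)^2))
  spectral_dataset(wl, A, data.frame(sample_id = c("a", "b"),
                                     group_label = c("A", "B")))
}

# noiseless four-band reference ladder shared by temperature-mode tests
ref_noiseless <- function(seed = 101) {
  simulate_temperature_series(noiseless(nir_water_model("four_band")),
                              seed = seed)
}

expect_aquagram_shape <- function(aq, n_groups, mode) {
  df <- as.data.frame(aq)
  df <- df[df$mode == mode, ]
  expect_equal(nrow(df), n_groups * 12)
  expect_true(all(df$lcl95 <= df$value + 1e-12, na.rm = TRUE))
  expect_true(all(df$value <= df$ucl95 + 1e-12, na.rm = TRUE))
}
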