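#' Synthetic water NIR spectrum model
#'
#' A generative model of the water first overtone band (1300--1600 nm) used
#' to validate the aquagram pipeline without instrument data. The spectrum
#' is a sum of Gaussian species bands whose amplitudes respond linearly to
#' temperature, on a linear baseline, with per-spectrum multiplicative and
#' additive scatter and i.i.d. photometric noise. The temperature
#' coefficients conserve the total band area, which gives the model the two
#' qualitative signatures of real water spectra under heating: a blue shift
#' of the band maximum and an isosbestic (temperature-invariant) point
#' between the growing and shrinking bands.
#'
#' Two built-in variants:
#' * `"two_band"` (default): the minimal mechanism -- the 1412 nm
#'   (weakly hydrogen-bonded) band grows with temperature while the 1462 nm
#'   (hydrogen-bonded) band shrinks, with area-conserving rates.
#' * `"four_band"`: adds broad flanking species bands near 1360 nm
#'   (free OH / small clusters) and 1490 nm (strongly hydrogen-bonded
#'   S3/S4), which gives every one of the 12 WAMACs a usable temperature
#'   response. Band strengths are calibrated to yield well-conditioned
#'   calibration slopes, not to mimic real water quantitatively.
#'
#' @param variant `"two_band"` or `"four_band"`, ignored when `bands` is
#'   given.
#' @param bands optional `data.frame` with columns `center_nm`, `sigma_nm`,
#'   `amplitude` (at `T_ref`) and `dA_dC` (amplitude change per degree C).
#' @param T_ref temperature (C) at which `amplitude` applies.
#' @param baseline named vector `c(offset, slope)`; absorbance baseline is
#'   `offset + slope * (lambda - 1450)`.
#' @param scatter named vector `c(mult_sd, add_sd)`: per-spectrum
#'   multiplicative (around 1) and additive scatter SDs.
#' @param noise_sd photometric noise SD in absorbance units.
#' @return An object of class `nir_water_model`.
#' @examples
#' nir_water_model()
#' nir_water_model("four_band", noise_sd = 0)
#' @export
nir_water_model <- function(variant = c("two_band", "four_band"),
                            bands = NULL, T_ref = 45,
                            baseline = c(offset = 0.25, slope = 1e-4),
                            scatter = c(mult_sd = 0.02, add_sd = 0.005),
                            noise_sd = 0.002) {
  if (is.null(bands)) {
    variant <- match.arg(variant)
    bands <- switch(variant,
      two_band = data.frame(
        center_nm = c(1412, 1462), sigma_nm = c(16, 20),
        amplitude = c(0.55, 0.75), dA_dC = c(0.0040, -0.0032)),
      four_band = data.frame(
        center_nm = c(1360, 1412, 1462, 1490),
        sigma_nm  = c(28, 14, 14, 20),
        amplitude = c(0.35, 0.60, 0.80, 0.35),
        dA_dC     = c(0.012, 0.009, -0.2220 / 14, -0.012)))
  } else variant <- "custom"
  bands <- as.data.frame(bands)
  stopifnot(all(c("center_nm", "sigma_nm", "amplitude", "dA_dC") %in%
                  names(bands)))
  if (any(bands$sigma_nm <= 0) || any(bands$amplitude < 0))
    stop("model error: need sigma_nm > 0 and amplitude >= 0", call. = FALSE)
  structure(list(bands = bands, T_ref = T_ref,
                 baseline = baseline, scatter = scatter,
                 noise_sd = noise_sd, variant = variant),
            class = "nir_water_model")
}

#' @export
print.nir_water_model <- function(x, ...) {
  cat("<nir_water_model> variant '", x$variant, "', T_ref = ", x$T_ref,
      " C, noise_sd = ", x$noise_sd, "\n", sep = "")
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' @rdname nir_water_model
#' @param model a `nir_water_model`.
#' @return `noiseless()` returns the model with scatter and photometric
#'   noise switched off.
#' @export
noiseless <- function(model) {
  model$scatter[] <- 0
  model$noise_sd <- 0
  model
}

gauss_mat <- function(wl, centers, sigmas) {
  # length(wl) x n_bands matrix of unit-amplitude Gaussian profiles
  vapply(seq_along(centers),
         function(i) exp(-0.5 * ((wl - centers[i]) / sigmas[i])^2),
         numeric(length(wl)))
}

# deterministic part of the spectrum at temperature TT (vector over wl)
model_spectrum <- function(model, wl, TT, extra = NULL) {
  amp <- model$bands$amplitude + model$bands$dA_dC * (TT - model$T_ref)
  if (any(amp < 0))
    stop("model error: negative band amplitude at ", TT, " C", call. = FALSE)
  y <- as.vector(gauss_mat(wl, model$bands$center_nm,
                           model$bands$sigma_nm) %*% amp)
  if (!is.null(extra) && nrow(extra))
    y <- y + as.vector(gauss_mat(wl, extra$center_nm, extra$sigma_nm) %*%
                         extra$amplitude)
  y + model$baseline[["offset"]] + model$baseline[["slope"]] * (wl - 1450)
}

apply_scatter_noise <- function(clean, model) {
  # one multiplicative/additive scatter draw per spectrum (never per
  # wavelength) so MSC can remove it exactly; then i.i.d. photometric noise
  a <- 1 + rnorm(1, 0, model$scatter[["mult_sd"]])
  b <- rnorm(1, 0, model$scatter[["add_sd"]])
  a * clean + b + rnorm(length(clean), 0, model$noise_sd)
}

#' Simulate a pure-water temperature series
#'
#' Emulates the reference experiment of the temperature-based aquagram:
#' spectra of pure water at a ladder of temperatures (default 20--70 C in
#' 2 C increments, i.e. 26 steps) with a number of consecutive scans per
#' step (default 3, hence 78 spectra). Scans at one temperature share the
#' deterministic spectrum and differ by their scatter and noise draws.
#'
#' @param model a [nir_water_model()].
#' @param temps temperatures in degrees C.
#' @param n_scans consecutive scans per temperature.
#' @param grid `c(lo, hi, step)` wavelength grid in nm; must cover
#'   1300--1600.
#' @param seed integer seed; fixed seed gives identical output.
#' @return A [spectral_dataset()] with `group_label` (formatted
#'   temperature), `temperature_C`, `replicate_id` and `scan_index`
#'   metadata.
#' @export
simulate_temperature_series <- function(model, temps = seq(20, 70, by = 2),
                                        n_scans = 3,
                                        grid = c(1300, 1600, 0.5),
                                        seed = NULL) {
  stopifnot(inherits(model, "nir_water_model"))
  if (grid[1] > 1300 || grid[2] < 1600)
    stop("grid must cover 1300-1600 nm", call. = FALSE)
  wl <- seq(grid[1], grid[2], by = grid[3])
  with_seed(seed, {
    rows <- list(); meta <- list(); k <- 0
    for (TT in temps) {
      clean <- model_spectrum(model, wl, TT)
      for (s in seq_len(n_scans)) {
        k <- k + 1
        rows[[k]] <- apply_scatter_noise(clean, model)
        meta[[k]] <- data.frame(
          sample_id = sprintf("T%g_scan%d", TT, s),
          group_label = sprintf("T%g", TT), temperature_C = TT,
          replicate_id = 1L, scan_index = s, stringsAsFactors = FALSE)
      }
    }
    spectral_dataset(wl, do.call(rbind, rows), do.call(rbind, meta),
                     declared_step = grid[3])
  })
}

#' Locate the isosbestic point of a water model
#'
#' Grid search for the temperature-invariant wavelength of the noiseless
#' model: the grid point (restricted to where the band signal is
#' non-negligible, so the flat baseline outside the bands does not win)
#' with minimal absorbance variance across the temperature ladder. With
#' area-conserving temperature coefficients this variance is numerically
#' zero and the point sits between the growing and the shrinking band.
#'
#' @param model a [nir_water_model()].
#' @param temps temperatures to scan.
#' @param grid wavelength grid `c(lo, hi, step)` in nm.
#' @param min_rel_signal fraction of the peak band absorbance below which a
#'   wavelength is excluded from the search.
#' @return A list with `wavelength_nm`, `sd` (absorbance SD across
#'   temperatures there) and `peak` (maximal band absorbance).
#' @export
isosbestic_wavelength <- function(model, temps = seq(20, 70, by = 2),
                                  grid = c(1300, 1600, 0.5),
                                  min_rel_signal = 0.01) {
  wl <- seq(grid[1], grid[2], by = grid[3])
  m0 <- noiseless(model)
  S <- vapply(temps, function(TT) model_spectrum(m0, wl, TT), numeric(length(wl)))
  base <- model$baseline[["offset"]] + model$baseline[["slope"]] * (wl - 1450)
  band <- S - base                    # band signal without the baseline
  peak <- max(band)
  ok <- rowMeans(band) >= min_rel_signal * peak
  sds <- apply(S, 1, sd)
  i <- which(ok)[which.min(sds[ok])]
  list(wavelength_nm = wl[i], sd = sds[i], peak = peak)
}

#' Solute perturbation of the water spectral pattern
#'
#' A solute effect is a set of signed Gaussian perturbation components
#' added to the water spectrum in proportion to a monotone function of
#' concentration. The built-in `structure_breaker()` emulates an ion like
#' KCl: the hydrogen-bonded network bands in the core of the first
#' overtone (around 1450 and 1467 nm, the S1/S2 species) are depleted,
#' free / weakly bonded OH (1360, 1412 nm) is created, and -- because the
#' dissolved ions displace water -- the depletion exceeds the gains, so
#' the total band area decreases with concentration. The band ranges at
#' the edges of the region then lose less than the average and their
#' *relative* areas grow, which is what produces temperature equivalents
#' of opposite sign at the low- and high-wavelength coordinates.
#' `structure_maker()` is the sign-reversed effect (a solute acting like
#' cooling).
#'
#' @param components `data.frame` with columns `center_nm`, `sigma_nm`,
#'   `dA_per_effect` (amplitude per unit effect; the effect of
#'   concentration `c` mM is `log10(1 + c)` by default).
#' @param conc_map function mapping concentration (mM) to effect units.
#' @return An object of class `solute_effect`.
#' @export
solute_effect <- function(components, conc_map = function(c) log10(1 + c)) {
  components <- as.data.frame(components)
  stopifnot(all(c("center_nm", "sigma_nm", "dA_per_effect") %in%
                  names(components)))
  structure(list(components = components, conc_map = conc_map),
            class = "solute_effect")
}

#' @rdname solute_effect
#' @export
structure_breaker <- function() {
  solute_effect(data.frame(
    center_nm = c(1360, 1412, 1450, 1467),
    sigma_nm  = c(28, 14, 9, 6),
    dA_per_effect = c(0.0008, 0.0030, -0.0110, -0.0030)))
}

#' @rdname solute_effect
#' @export
structure_maker <- function() {
  e <- structure_breaker()
  e$components$dA_per_effect <- -e$components$dA_per_effect
  e
}

#' Simulate an aqueous-solution concentration series
#'
#' Emulates the solute experiment: solutions at a ladder of concentrations
#' measured at a fixed incubation temperature, in independently prepared
#' replicate series with consecutive scans, interleaved with pure-water
#' control samples. The defaults reproduce the canonical design: three
#' serial-dilution ranges (100--1000 by 100, 10--100 by 10, 1--10 by 1 mM;
#' 30 samples) x 2 replicates x 3 scans, plus 50 control samples x 3 scans
#' = 330 spectra.
#'
#' @param model a [nir_water_model()] (the `"four_band"` variant gives all
#'   coordinates a temperature response and is recommended here).
#' @param concentrations_mM concentrations in mM.
#' @param effect a [solute_effect()].
#' @param experiment_T measurement temperature in degrees C.
#' @param n_reps independently prepared replicate series.
#' @param n_scans consecutive scans per sample.
#' @param n_controls number of pure-water control samples (each scanned
#'   `n_scans` times), interleaved among the solutions.
#' @param grid wavelength grid `c(lo, hi, step)` in nm.
#' @param seed integer seed.
#' @return A [spectral_dataset()]; controls have `group_label = "MilliQ"`
#'   and `concentration_mM = 0`, solutions are labelled by concentration.
#' @export
simulate_solute_series <- function(model = nir_water_model("four_band"),
                                   concentrations_mM =
                                     c(seq(100, 1000, by = 100),
                                       seq(10, 100, by = 10), 1:10),
                                   effect = structure_breaker(),
                                   experiment_T = 28, n_reps = 2,
                                   n_scans = 3, n_controls = 50,
                                   grid = c(1300, 1600, 0.5), seed = NULL) {
  stopifnot(inherits(model, "nir_water_model"),
            inherits(effect, "solute_effect"))
  wl <- seq(grid[1], grid[2], by = grid[3])
  with_seed(seed, {
    rows <- list(); meta <- list(); k <- 0
    emit <- function(conc, rep_id) {
      ec <- effect$conc_map(conc)
      extra <- effect$components
      extra$amplitude <- extra$dA_per_effect * ec
      clean <- model_spectrum(model, wl, experiment_T, extra = extra)
      if (any(clean < 0))
        stop("model error: negative absorbance at concentration ", conc,
             " mM", call. = FALSE)
      for (s in seq_len(n_scans)) {
        k <<- k + 1
        rows[[k]] <<- apply_scatter_noise(clean, model)
        meta[[k]] <<- data.frame(
          sample_id = sprintf("c%g_r%d_scan%d", conc, rep_id, s),
          group_label = if (conc == 0) "MilliQ" else sprintf("%gmM", conc),
          temperature_C = experiment_T, concentration_mM = conc,
          replicate_id = rep_id, scan_index = s, stringsAsFactors = FALSE)
      }
    }
    # interleave: controls measured as every (n_samples/n_controls)-th sample
    samples <- expand.grid(rep = seq_len(n_reps), conc = concentrations_mM)
    ctrl_every <- max(1L, floor(nrow(samples) / max(1L, n_controls)))
    ctrl_left <- n_controls
    for (i in seq_len(nrow(samples))) {
      emit(samples$conc[i], samples$rep[i])
      if (ctrl_left > 0 && i %% ctrl_every == 0) {
        emit(0, 0L); ctrl_left <- ctrl_left - 1
      }
    }
    while (ctrl_left > 0) { emit(0, 0L); ctrl_left <- ctrl_left - 1 }
    spectral_dataset(wl, do.call(rbind, rows), do.call(rbind, meta),
                     declared_step = grid[3])
  })
}
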