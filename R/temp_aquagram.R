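# shared fast path: mean spectra (rows of M) -> baseline-corrected relative
# areas, fully vectorized through the fixed quadrature weight matrix.
area_machine <- function(wavelengths, scheme, window = c(1300, 1600)) {
  W <- vapply(seq_len(nrow(scheme)), function(i)
    trapz_weights(wavelengths, scheme$lo_nm[i], scheme$hi_nm[i]),
    numeric(length(wavelengths)))
  colnames(W) <- scheme$id
  wt <- trapz_weights(wavelengths, window[1], window[2])
  i0 <- which(abs(wavelengths - window[1]) <= 1e-6)
  i1 <- which(abs(wavelengths - window[2]) <= 1e-6)
  if (length(i0) != 1 || length(i1) != 1)
    stop("range error: grid must contain ", window[1], " and ", window[2],
         " nm", call. = FALSE)
  frac <- (wavelengths - window[1]) / (window[2] - window[1])
  function(M) {
    y0 <- M[, i0]; y1 <- M[, i1]
    B <- M - outer(y0, rep(1, ncol(M))) - outer(y1 - y0, frac)
    total <- as.vector(B %*% wt)
    if (any(total <= 0))
      stop("degenerate-spectrum error: non-positive total area",
           call. = FALSE)
    (B %*% W) / total
  }
}

#' Temperature-based aquagram
#'
#' Expresses the water spectral pattern of each experimental group as the
#' equivalent temperature change in pure water, in degrees Celsius. The
#' chain per group is: subtract the two-edge baseline over 1300--1600 nm;
#' integrate the 12 coordinate ranges and normalize each spectrum by its
#' full first overtone area ([relative_areas()]); average the relative
#' areas over the group's spectra (normalizing before averaging is what
#' makes per-spectrum scatter and pathlength effects cancel exactly); and
#' invert, per coordinate, the local linear calibration fitted to the
#' smoothed relative-area-versus-temperature curves built from the
#' pure-water reference series ([build_reference_curves()],
#' [local_calibration()]). Confidence limits come from resampling the
#' group's spectra with replacement and pushing each resample through the
#' whole chain; the reference dataset is treated as a fixed calibration
#' and never resampled.
#'
#' Because every group is processed only through its own spectra and the
#' fixed reference, the values are stable under any recomposition of the
#' experimental dataset -- adding or removing unrelated groups does not
#' change a group's pattern, unlike the classic aquagram.
#'
#' @param experimental a [spectral_dataset()] with the groups of interest.
#' @param reference pure-water temperature series with `temperature_C`
#'   metadata (e.g. 26 steps of 2 C between 20 and 70 C, 3 scans each).
#' @param group_key metadata column defining the experimental groups.
#' @param scheme a [wamac_scheme()].
#' @param experiment_T temperature (C) at which the experiment was
#'   performed; the calibration window is `experiment_T +/- halfwidth`.
#'   `NULL` (default) calibrates each group at its own `temperature_C`
#'   metadata value, which is what a temperature experiment itself needs so
#'   the whole 20--70 C span stays representable.
#' @param control_group optional group label; when given (requires a single
#'   `experiment_T`), delta rows (`group - control`, with bootstrap CIs of
#'   the difference) are appended with `mode = "delta"`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @param span,degree,fine_step smoothing settings, see
#'   [build_reference_curves()].
#' @param halfwidth,beta_min,beta_min_frac calibration window and
#'   conditioning, see [local_calibration()].
#' @param level confidence level.
#' @return An object of class `aquagram` with one row per (group,
#'   coordinate); `value` is in degrees C, ill-conditioned coordinates are
#'   reported as `NA` with `conditioned = FALSE`. The calibration is
#'   attached as attribute `"calibration"`.
#' @examples
#' m <- nir_water_model()
#' ref <- simulate_temperature_series(m, seed = 1)
#' exp <- simulate_temperature_series(m, temps = c(27, 29), n_scans = 6,
#'                                    seed = 2)
#' temp_aquagram(exp, ref, experiment_T = 28, n_boot = 200, seed = 3)
#' @export
temp_aquagram <- function(experimental, reference,
                          group_key = "group_label",
                          scheme = default_wamac_scheme(),
                          experiment_T = NULL, control_group = NULL,
                          n_boot = 1000, seed = NULL,
                          span = 0.5, degree = 2, fine_step = 0.1,
                          halfwidth = 2, beta_min = NULL,
                          beta_min_frac = 0.05, level = 0.95) {
  stopifnot(inherits(experimental, "spectral_dataset"),
            inherits(reference, "spectral_dataset"))
  if (!group_key %in% names(experimental$meta))
    stop("group_key '", group_key, "' not in experimental metadata",
         call. = FALSE)
  experimental <- subset_wavelengths(experimental, 1300, 1600)
  reference <- subset_wavelengths(reference, 1300, 1600)
  curves <- build_reference_curves(reference, scheme, span, degree,
                                   fine_step)
  grp <- factor(experimental$meta[[group_key]],
                levels = unique(experimental$meta[[group_key]]))
  if (any(tabulate(grp) == 0)) stop("empty group", call. = FALSE)
  per_group_T <- is.null(experiment_T)
  if (per_group_T) {
    tc <- experimental$meta$temperature_C
    if (is.null(tc) || anyNA(tc))
      stop("experiment_T is NULL but experimental metadata has no ",
           "complete temperature_C column", call. = FALSE)
    group_T <- vapply(levels(grp), function(g) {
      u <- unique(tc[grp == g])
      if (length(u) != 1)
        stop("group '", g, "' has multiple temperatures; give experiment_T",
             call. = FALSE)
      u
    }, numeric(1))
  } else {
    if (!is.null(control_group) && length(experiment_T) != 1)
      stop("delta reporting needs a single experiment_T", call. = FALSE)
    group_T <- setNames(rep(experiment_T[1], nlevels(grp)), levels(grp))
  }
  ra_of <- area_machine(experimental$wavelengths, scheme)
  calibs <- lapply(unique(group_T), function(tt)
    local_calibration(curves, tt, halfwidth, beta_min, beta_min_frac))
  names(calibs) <- as.character(unique(group_T))

  one_group <- function(g) {
    calib <- calibs[[as.character(group_T[[g]])]]
    X <- experimental$absorbance[grp == g, , drop = FALSE]
    ng <- nrow(X)
    # normalize per spectrum, then average the relative areas: this is what
    # makes multiplicative scatter cancel exactly instead of reweighting
    # the group mean spectrum
    R <- ra_of(X)
    r <- matrix(colMeans(R), nrow = 1)
    val <- as.vector(temperature_equivalent(calib, r))
    if (ng == 1) {
      reps <- matrix(val, 1, length(val), byrow = TRUE)
    } else {
      reps_r <- boot_counts(ng, n_boot) %*% R / ng
      reps <- temperature_equivalent(calib, reps_r)
    }
    b <- percentile_bounds(reps, level)
    list(df = data.frame(group = g, coordinate = scheme$id,
                         center_nm = scheme$center_nm, value = val,
                         lcl95 = pmin(b$lower, val),
                         ucl95 = pmax(b$upper, val),
                         n = ng, conditioned = unname(calib$conditioned),
                         mode = "absolute", stringsAsFactors = FALSE),
         reps = reps)
  }

  res <- with_seed(seed, {
    parts <- lapply(levels(grp), one_group)
    names(parts) <- levels(grp)
    df <- do.call(rbind, lapply(parts, `[[`, "df"))
    if (!is.null(control_group)) {
      if (!control_group %in% levels(grp))
        stop("control_group '", control_group, "' not among groups",
             call. = FALSE)
      ctrl <- parts[[control_group]]
      deltas <- lapply(setdiff(levels(grp), control_group), function(g) {
        d <- parts[[g]]$df
        dreps <- parts[[g]]$reps - ctrl$reps
        dval <- d$value - ctrl$df$value
        b <- percentile_bounds(dreps, level)
        d$value <- dval
        d$lcl95 <- pmin(b$lower, dval)
        d$ucl95 <- pmax(b$upper, dval)
        d$conditioned <- d$conditioned & ctrl$df$conditioned
        d$mode <- "delta"
        d
      })
      df <- rbind(df, do.call(rbind, deltas))
    }
    df
  })
  out <- new_aquagram(res, mode = "temperature", scheme = scheme,
                      units = "degC", level = level)
  attr(out, "calibration") <- calibs
  attr(out, "reference_curves") <- curves
  out
}
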