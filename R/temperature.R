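# trapezoid quadrature weights over the grid points inside [lo, hi];
# returns a length-p vector w such that area = spectrum %*% w.
trapz_weights <- function(wavelengths, lo, hi, tol = 1e-6) {
  p <- length(wavelengths)
  keep <- which(wavelengths >= lo - tol & wavelengths <= hi + tol)
  if (length(keep) < 2)
    stop("range [", lo, ", ", hi, "] nm covers fewer than 2 grid points",
         call. = FALSE)
  w <- numeric(p)
  d <- diff(wavelengths[keep])
  w[keep] <- c(d / 2, 0) + c(0, d / 2)
  w
}

#' Baseline correction by the two-edge line
#'
#' Subtracts from every spectrum the straight line through its values at the
#' two edges of the first overtone region (1300 and 1600 nm by default), so
#' the corrected spectrum is exactly zero at both anchors. This is the
#' baseline step of the temperature-based aquagram: a spectrum that is
#' linear over the window becomes identically zero. Optionally each anchor
#' is the mean over a small window around the edge for noise robustness.
#'
#' @param ds a [spectral_dataset()] whose grid contains both edges.
#' @param edges the two anchor wavelengths in nm.
#' @param anchor_halfwidth half-width (nm) of the averaging window around
#'   each anchor; 0 (default) uses the single grid point.
#' @return The corrected `spectral_dataset` restricted to `[edges[1],
#'   edges[2]]`.
#' @export
baseline_correct <- function(ds, edges = c(1300, 1600),
                             anchor_halfwidth = 0) {
  stopifnot(inherits(ds, "spectral_dataset"))
  for (e in edges)
    if (!any(abs(ds$wavelengths - e) <= 1e-6))
      stop("range error: grid does not contain the edge wavelength ", e,
           " nm", call. = FALSE)
  ds <- subset_wavelengths(ds, edges[1], edges[2])
  anchor <- function(e) {
    if (anchor_halfwidth > 0) {
      k <- which(abs(ds$wavelengths - e) <= anchor_halfwidth + 1e-6)
      rowMeans(ds$absorbance[, k, drop = FALSE])
    } else ds$absorbance[, wl_index(ds, e)]
  }
  y0 <- anchor(edges[1]); y1 <- anchor(edges[2])
  frac <- (ds$wavelengths - edges[1]) / (edges[2] - edges[1])
  A <- ds$absorbance - outer(y0, rep(1, length(frac))) -
    outer(y1 - y0, frac)
  spectral_dataset(ds$wavelengths, A, ds$meta)
}

#' Relative band areas at the WAMACs
#'
#' Integrates each (baseline-corrected) spectrum over every coordinate range
#' and over the full first overtone window by the trapezoidal rule on the
#' native grid, and reports each coordinate area as a fraction of the total.
#' The normalization makes the result invariant to any positive scaling of
#' the spectrum, which is what removes pathlength and multiplicative scatter
#' effects from the temperature-based aquagram.
#'
#' @param ds a [spectral_dataset()] covering 1300--1600 nm,
#'   baseline-corrected (see [baseline_correct()]).
#' @param scheme a [wamac_scheme()].
#' @param window full-region integration bounds in nm.
#' @return A list with `rel_area` (n x n_coord matrix of fractions), `auc`
#'   (n x n_coord, nm x absorbance) and `total_auc` (length n).
#' @export
relative_areas <- function(ds, scheme = default_wamac_scheme(),
                           window = c(1300, 1600)) {
  stopifnot(inherits(ds, "spectral_dataset"))
  W <- vapply(seq_len(nrow(scheme)), function(i)
    trapz_weights(ds$wavelengths, scheme$lo_nm[i], scheme$hi_nm[i]),
    numeric(length(ds$wavelengths)))
  wt <- trapz_weights(ds$wavelengths, window[1], window[2])
  auc <- ds$absorbance %*% W
  total <- as.vector(ds$absorbance %*% wt)
  if (any(total <= 0))
    stop("degenerate-spectrum error: non-positive total area for spectrum ",
         which(total <= 0)[1], call. = FALSE)
  colnames(auc) <- scheme$id
  list(rel_area = auc / total, auc = auc, total_auc = total)
}

#' Smoothed relative-area-versus-temperature reference curves
#'
#' From a pure-water temperature series, builds for every coordinate a
#' smooth curve of relative area against temperature: consecutive scans are
#' averaged per temperature step, spectra are baseline-corrected, relative
#' areas computed, and a locally weighted polynomial regression (tricube
#' weights, degree 2 by default, span as a fraction of points) is evaluated
#' on a uniform fine temperature grid. These curves are the backbone of the
#' temperature-based aquagram.
#'
#' @param reference a [spectral_dataset()] with a `temperature_C` metadata
#'   column and at least 5 distinct temperatures.
#' @param scheme a [wamac_scheme()].
#' @param span smoother span (fraction of points used per local fit).
#' @param degree local polynomial degree (1 or 2).
#' @param fine_step fine temperature grid step in degrees C.
#' @return An object of class `reference_curves`: list with `T_grid`,
#'   `curves` (matrix, length(T_grid) x n_coord), per-coordinate residual
#'   SD `resid_sd`, the raw per-temperature `rel_area` and settings.
#' @export
build_reference_curves <- function(reference, scheme = default_wamac_scheme(),
                                   span = 0.5, degree = 2, fine_step = 0.1) {
  stopifnot(inherits(reference, "spectral_dataset"))
  if (is.null(reference$meta$temperature_C) ||
      anyNA(reference$meta$temperature_C))
    stop("reference dataset must carry temperature_C metadata",
         call. = FALSE)
  temps <- sort(unique(reference$meta$temperature_C))
  if (length(temps) < 5)
    stop("fit error: need >= 5 distinct reference temperatures",
         call. = FALSE)
  if (floor(span * length(temps)) < degree + 1)
    stop("fit error: span ", span, " leaves fewer than ", degree + 1,
         " points per local fit", call. = FALSE)
  # normalize per scan, then average relative areas per temperature step
  # (scan-order mean; makes per-scan multiplicative scatter cancel exactly)
  ra_all <- relative_areas(baseline_correct(reference), scheme)$rel_area
  ra <- t(vapply(temps, function(tt)
    colMeans(ra_all[reference$meta$temperature_C == tt, , drop = FALSE]),
    numeric(nrow(scheme))))
  T_grid <- seq(min(temps), max(temps), by = fine_step)
  fit_one <- function(y) {
    fit <- loess(y ~ temps, span = span, degree = degree,
                 surface = "direct",
                 control = loess.control(iterations = 1))
    list(curve = predict(fit, data.frame(temps = T_grid)),
         resid = sd(fit$residuals))
  }
  fits <- apply(ra, 2, fit_one)
  curves <- vapply(fits, `[[`, numeric(length(T_grid)), "curve")
  colnames(curves) <- scheme$id
  structure(list(T_grid = T_grid, curves = curves,
                 resid_sd = vapply(fits, `[[`, numeric(1), "resid"),
                 rel_area = ra, temps = temps, scheme = scheme,
                 span = span, degree = degree, fine_step = fine_step),
            class = "reference_curves")
}

#' @export
print.reference_curves <- function(x, ...) {
  cat("<reference_curves> ", ncol(x$curves), " coordinates, ",
      length(x$temps), " temperatures [", min(x$temps), ", ", max(x$temps),
      "] C, fine step ", x$fine_step, " C\n", sep = "")
  invisible(x)
}

#' Local temperature calibration at the experiment temperature
#'
#' Fits, for every coordinate, an ordinary least-squares line
#' `r(T) = alpha + beta * T` to the smoothed reference curve inside the
#' symmetric window `experiment_T +/- halfwidth` (a span of 4 degrees C by
#' default, e.g. 23--27 C for an experiment at 25 C). The slope `beta`
#' quantifies how fast the coordinate's relative area responds to
#' temperature; coordinates whose response is too weak -- near the
#' isosbestic point the slope legitimately approaches zero -- are flagged
#' as ill-conditioned rather than allowed to blow up into huge degree
#' equivalents.
#'
#' The conditioning default is relative: a coordinate is conditioned when
#' `|beta| >= beta_min_frac * max_c |beta_c|` within the same calibration.
#' An absolute `beta_min` (relative area per degree C) can be supplied
#' instead.
#'
#' @param curves a [build_reference_curves()] result.
#' @param experiment_T temperature of the experiment in degrees C.
#' @param halfwidth window half-width in degrees C (default 2).
#' @param beta_min absolute conditioning threshold, or `NULL` to use the
#'   relative rule.
#' @param beta_min_frac fraction of the strongest coordinate slope below
#'   which a coordinate is flagged ill-conditioned (default 0.05).
#' @return An object of class `temperature_calibration` with per-coordinate
#'   `alpha`, `beta`, `conditioned`, the window, and the curves.
#' @export
local_calibration <- function(curves, experiment_T, halfwidth = 2,
                              beta_min = NULL, beta_min_frac = 0.05) {
  stopifnot(inherits(curves, "reference_curves"))
  lo <- experiment_T - halfwidth; hi <- experiment_T + halfwidth
  tg <- curves$T_grid
  if (experiment_T < min(tg) - 1e-9 || experiment_T > max(tg) + 1e-9)
    stop("range error: experiment_T ", experiment_T,
         " outside curve span [", min(tg), ", ", max(tg), "] C",
         call. = FALSE)
  # for experiments near the ends of the reference ladder the symmetric
  # window is clamped to the curve span (asymmetric local fit)
  lo <- max(lo, min(tg)); hi <- min(hi, max(tg))
  if (hi - lo < halfwidth)
    stop("range error: window [", lo, ", ", hi, "] C too short after ",
         "clamping to the curve span", call. = FALSE)
  inw <- tg >= lo - 1e-9 & tg <= hi + 1e-9
  tc <- tg[inw] - mean(tg[inw])
  Y <- curves$curves[inw, , drop = FALSE]
  beta <- as.vector(crossprod(tc, sweep(Y, 2, colMeans(Y))) / sum(tc^2))
  alpha <- colMeans(Y) - beta * mean(tg[inw])
  thr <- if (!is.null(beta_min)) beta_min else beta_min_frac * max(abs(beta))
  structure(list(alpha = setNames(alpha, colnames(Y)),
                 beta = setNames(beta, colnames(Y)),
                 conditioned = setNames(abs(beta) >= thr, colnames(Y)),
                 beta_min = thr, window = c(lo, hi),
                 experiment_T = experiment_T, halfwidth = halfwidth,
                 curves = curves, scheme = curves$scheme),
            class = "temperature_calibration")
}

#' Fit a temperature calibration in one call
#'
#' Convenience wrapper: [build_reference_curves()] followed by
#' [local_calibration()].
#'
#' @inheritParams build_reference_curves
#' @inheritParams local_calibration
#' @export
temperature_calibration <- function(reference,
                                    experiment_T,
                                    scheme = default_wamac_scheme(),
                                    span = 0.5, degree = 2, fine_step = 0.1,
                                    halfwidth = 2, beta_min = NULL,
                                    beta_min_frac = 0.05) {
  local_calibration(
    build_reference_curves(reference, scheme, span, degree, fine_step),
    experiment_T, halfwidth, beta_min, beta_min_frac)
}

#' @export
print.temperature_calibration <- function(x, digits = 4, ...) {
  cat("<temperature_calibration> experiment_T = ", x$experiment_T,
      " C, window [", x$window[1], ", ", x$window[2], "] C\n", sep = "")
  print(data.frame(alpha = signif(x$alpha, digits),
                   beta = signif(x$beta, digits),
                   conditioned = x$conditioned))
  invisible(x)
}

#' @describeIn local_calibration calibration curves with the local window.
#' @param x a `temperature_calibration`.
#' @param coordinates coordinate ids to draw (default: all).
#' @param ... passed to [graphics::plot()].
#' @export
plot.temperature_calibration <- function(x, coordinates = NULL, ...) {
  cv <- x$curves
  ids <- if (is.null(coordinates)) colnames(cv$curves) else coordinates
  old <- par(mfrow = grDevices::n2mfrow(length(ids)), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (id in ids) {
    plot(cv$T_grid, cv$curves[, id], type = "l", xlab = "temperature (C)",
         ylab = "relative area", main = id, ...)
    points(cv$temps, cv$rel_area[, id], pch = 16, cex = 0.5)
    graphics::abline(v = x$window, lty = 3)
    graphics::abline(a = x$alpha[id], b = x$beta[id], col = 2, lty = 2)
  }
  invisible(x)
}

#' Temperature equivalent of a relative area
#'
#' Inverts the local calibration line of one or all coordinates:
#' `T_equiv = (r_star - alpha) / beta`. For an ill-conditioned coordinate
#' the value is suppressed (`NA`, or an error when a single coordinate is
#' requested) rather than fabricated from a near-zero slope.
#'
#' @param calib a [local_calibration()] result.
#' @param r_star relative area(s): a vector named or ordered as the scheme
#'   coordinates, or a matrix with one column per coordinate.
#' @param coordinate a single coordinate id (e.g. `"C05"`) to invert one
#'   coordinate strictly; `NULL` (default) inverts all.
#' @return Degrees Celsius: a scalar, vector or matrix matching `r_star`.
#' @export
temperature_equivalent <- function(calib, r_star, coordinate = NULL) {
  stopifnot(inherits(calib, "temperature_calibration"))
  if (!is.null(coordinate)) {
    if (!coordinate %in% names(calib$beta))
      stop("unknown coordinate ", coordinate, call. = FALSE)
    if (!calib$conditioned[coordinate])
      stop("conditioning error: coordinate ", coordinate,
           " has |beta| below ", format(calib$beta_min),
           " (near-isosbestic)", call. = FALSE)
    return((r_star - calib$alpha[[coordinate]]) / calib$beta[[coordinate]])
  }
  beta <- ifelse(calib$conditioned, calib$beta, NA_real_)
  if (is.matrix(r_star))
    sweep(sweep(r_star, 2, calib$alpha), 2, beta, "/")
  else (r_star - calib$alpha) / beta
}

#' @export
predict.temperature_calibration <- function(object, newdata, ...) {
  temperature_equivalent(object, newdata)
}
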