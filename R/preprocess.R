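#' Multiplicative scatter correction
#'
#' Removes per-spectrum affine (scatter / pathlength) distortions by
#' ordinary least-squares regression of each spectrum on a reference
#' spectrum: with fitted slope `a` and intercept `b`, the corrected spectrum
#' is `(x - b) / a`. The default reference is the mean spectrum of the
#' dataset. The fit uses all wavelengths present, so apply
#' [subset_wavelengths()] first if the correction should be restricted to
#' the first overtone window.
#'
#' @param ds a [spectral_dataset()].
#' @param reference numeric vector of length `ncol(ds$absorbance)`, or
#'   `NULL` for the mean spectrum (requires at least 2 spectra).
#' @return The corrected `spectral_dataset`, with the per-spectrum fit
#'   stored in attribute `"msc_coefficients"` (a `data.frame` with columns
#'   `a`, `b`) and the reference in attribute `"msc_reference"`.
#' @export
msc <- function(ds, reference = NULL) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (is.null(reference)) {
    if (n_spectra(ds) < 2)
      stop("msc needs >= 2 spectra when no reference is supplied",
           call. = FALSE)
    reference <- colMeans(ds$absorbance)
  }
  reference <- as.numeric(reference)
  if (length(reference) != ncol(ds$absorbance))
    stop("reference length does not match the wavelength grid", call. = FALSE)
  vr <- var(reference)
  if (!is.finite(vr) || vr <= 0)
    stop("degenerate-fit error: reference spectrum has zero variance",
         call. = FALSE)
  rc <- reference - mean(reference)
  X <- ds$absorbance
  a <- as.vector(X %*% rc) / sum(rc^2)        # OLS slope per spectrum
  b <- rowMeans(X) - a * mean(reference)
  if (any(a == 0))
    stop("degenerate-fit error: zero slope for spectrum ",
         which(a == 0)[1], call. = FALSE)
  out <- spectral_dataset(ds$wavelengths, (X - b) / a, ds$meta)
  attr(out, "msc_coefficients") <- data.frame(a = a, b = b)
  attr(out, "msc_reference") <- reference
  out
}

#' Standard normal variate
#'
#' Centers every spectrum by its own mean across wavelengths and divides by
#' its own sample standard deviation (n - 1). Idempotent.
#'
#' @param ds a [spectral_dataset()].
#' @return The transformed `spectral_dataset`.
#' @export
snv <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  X <- ds$absorbance
  s <- apply(X, 1, sd)
  if (any(s == 0))
    stop("degenerate error: constant spectrum at row ", which(s == 0)[1],
         call. = FALSE)
  spectral_dataset(ds$wavelengths, (X - rowMeans(X)) / s, ds$meta)
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Per-spectrum Savitzky-Golay filtering with respect to wavelength: the
#' result is scaled by the grid step so a derivative of order `deriv` is in
#' units of absorbance per nm^deriv, independent of grid density. Within
#' half a window of either end the moving window no longer fits; these edge
#' values come from the polynomial fitted to the first/last full window and
#' the affected column indices are flagged in attribute `"sg_edge_region"`.
#'
#' The defaults (2nd order polynomial, 21 points, 2nd derivative) are the
#' usual settings for resolving the overlapping water species bands of the
#' first overtone -- on water spectra the 2nd derivative shows minima near
#' 1412 and 1462 nm.
#'
#' @param ds a [spectral_dataset()] on a uniform grid.
#' @param window odd number of filter points, greater than `polyorder`.
#' @param polyorder polynomial order, at least `deriv`.
#' @param deriv derivative order (0 = smoothing).
#' @return The filtered `spectral_dataset`.
#' @export
sg_derivative <- function(ds, window = 21, polyorder = 2, deriv = 2) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (window %% 2 != 1 || window <= polyorder || polyorder < deriv ||
      deriv < 0)
    stop("parameter error: need odd window > polyorder >= deriv >= 0",
         call. = FALSE)
  p <- length(ds$wavelengths)
  if (p < window)
    stop("parameter error: spectrum length ", p, " below window ", window,
         call. = FALSE)
  steps <- diff(ds$wavelengths)
  h <- steps[1]
  if (max(abs(steps - h)) > 1e-9)
    stop("sg_derivative requires a uniform wavelength grid", call. = FALSE)
  Y <- t(apply(ds$absorbance, 1, signal::sgolayfilt,
               p = polyorder, n = window, m = deriv, ts = h))
  if (n_spectra(ds) == 1) Y <- matrix(Y, nrow = 1)
  out <- spectral_dataset(ds$wavelengths, Y, ds$meta)
  half <- (window - 1) / 2
  attr(out, "sg_edge_region") <- c(seq_len(half), seq(p - half + 1, p))
  out
}

#' Principal component analysis of spectra
#'
#' Column-mean-centered PCA (no scaling) for exploratory analysis: the first
#' component of a temperature or concentration series typically captures the
#' perturbation itself (>99% of variance for water series).
#'
#' @param ds a [spectral_dataset()] with at least 2 spectra.
#' @param ncomp number of components, at most `min(n - 1, p)`.
#' @return A list with `scores` (n x ncomp), `loadings` (p x ncomp) and
#'   `explained` (fractions of total variance, non-increasing, summing to
#'   at most 1).
#' @export
pca_explained <- function(ds, ncomp = 2) {
  stopifnot(inherits(ds, "spectral_dataset"))
  n <- n_spectra(ds); p <- length(ds$wavelengths)
  if (n < 2) stop("pca needs >= 2 spectra", call. = FALSE)
  if (ncomp < 1 || ncomp > min(n - 1, p))
    stop("parameter error: ncomp must be in [1, ", min(n - 1, p), "]",
         call. = FALSE)
  fit <- prcomp(ds$absorbance, center = TRUE, scale. = FALSE)
  list(scores   = fit$x[, seq_len(ncomp), drop = FALSE],
       loadings = fit$rotation[, seq_len(ncomp), drop = FALSE],
       explained = (fit$sdev^2 / sum(fit$sdev^2))[seq_len(ncomp)])
}
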