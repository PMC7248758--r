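#' Spectral dataset container
#'
#' The universal currency of the package: a strictly increasing wavelength
#' grid (nm), an absorbance matrix (one row per spectrum, `logT^-1`,
#' dimensionless) and per-row metadata. Recognized metadata columns are
#' `sample_id`, `group_label`, `temperature_C`, `concentration_mM`,
#' `replicate_id` and `scan_index`; all are optional except `sample_id`,
#' which is generated when absent. Operations that require a field (e.g. the
#' reference dataset of [temp_aquagram()] requires `temperature_C`) fail fast
#' when it is missing.
#'
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing, no duplicates.
#' @param absorbance numeric matrix with `length(wavelengths)` columns, one
#'   row per spectrum. A single spectrum may be given as a vector.
#' @param meta `data.frame` with one row per spectrum, or `NULL`.
#' @param declared_step if non-`NULL`, the grid is validated to be uniform at
#'   this step (max deviation of consecutive differences below 1e-9 nm).
#' @return An object of class `spectral_dataset`: a list with elements
#'   `wavelengths`, `absorbance`, `meta`.
#' @examples
#' ds <- spectral_dataset(seq(1300, 1600, 0.5),
#'                        matrix(runif(2 * 601), nrow = 2))
#' ds
#' @export
spectral_dataset <- function(wavelengths, absorbance, meta = NULL,
                             declared_step = NULL) {
  wavelengths <- as.numeric(wavelengths)
  if (is.null(dim(absorbance))) absorbance <- matrix(absorbance, nrow = 1)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  n <- nrow(absorbance)
  if (ncol(absorbance) != length(wavelengths))
    stop("absorbance has ", ncol(absorbance), " columns but there are ",
         length(wavelengths), " wavelengths", call. = FALSE)
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing (validation error)",
         call. = FALSE)
  if (!all(is.finite(absorbance)))
    stop("absorbance contains non-finite values (validation error)",
         call. = FALSE)
  if (!is.null(declared_step) && length(wavelengths) > 1) {
    dev <- max(abs(diff(wavelengths) - declared_step))
    if (dev >= 1e-9)
      stop("wavelength grid deviates from declared step ", declared_step,
           " nm by ", format(dev), " nm", call. = FALSE)
  }
  if (is.null(meta)) meta <- data.frame(sample_id = paste0("s", seq_len(n)),
                                        stringsAsFactors = FALSE)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != n)
    stop("meta has ", nrow(meta), " rows but there are ", n, " spectra",
         call. = FALSE)
  if (is.null(meta$sample_id)) meta$sample_id <- paste0("s", seq_len(n))
  rownames(meta) <- NULL
  dimnames(absorbance) <- NULL
  structure(list(wavelengths = wavelengths, absorbance = absorbance,
                 meta = meta),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  wl <- x$wavelengths
  cat("<spectral_dataset> ", nrow(x$absorbance), " spectra x ",
      length(wl), " wavelengths [", wl[1], ", ", wl[length(wl)], "] nm\n",
      sep = "")
  cat("  meta: ", paste(names(x$meta), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$absorbance)

n_spectra <- function(ds) nrow(ds$absorbance)

# index of the grid point matching wavelength `wl` within `tol` nm;
# no interpolation is ever performed implicitly.
wl_index <- function(ds, wl, tol = 1e-6) {
  i <- which(abs(ds$wavelengths - wl) <= tol)
  if (length(i) != 1)
    stop("wavelength ", wl, " nm not on the grid (tolerance ", tol, " nm)",
         call. = FALSE)
  i
}

subset_rows <- function(ds, idx) {
  spectral_dataset(ds$wavelengths, ds$absorbance[idx, , drop = FALSE],
                   ds$meta[idx, , drop = FALSE])
}

#' Restrict a dataset to a wavelength interval
#'
#' Keeps grid points with `lo <= lambda <= hi` (inclusive on both ends);
#' metadata is unchanged. The canonical use is cutting a full-range
#' measurement down to the first overtone window, 1300--1600 nm.
#'
#' @param ds a [spectral_dataset()].
#' @param lo,hi interval bounds in nm, `lo < hi` (equality selects a single
#'   grid point).
#' @param tol matching tolerance in nm.
#' @return A `spectral_dataset` on the restricted grid.
#' @export
subset_wavelengths <- function(ds, lo, hi, tol = 1e-6) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (lo > hi) stop("lo must not exceed hi", call. = FALSE)
  keep <- ds$wavelengths >= lo - tol & ds$wavelengths <= hi + tol
  if (!any(keep))
    stop("empty intersection of [", lo, ", ", hi, "] nm with the grid ",
         "(range error)", call. = FALSE)
  spectral_dataset(ds$wavelengths[keep], ds$absorbance[, keep, drop = FALSE],
                   ds$meta)
}

#' Average consecutive scans
#'
#' Collapses the dataset to one row per group of the metadata keys `by`,
#' taking the arithmetic mean spectrum over each group's rows. `scan_index`
#' is dropped and the number of averaged spectra is recorded in an `n_scans`
#' metadata column. Metadata columns constant within a group are carried
#' over; varying ones (other than `by`) are dropped.
#'
#' @param ds a [spectral_dataset()].
#' @param by character vector of metadata column names to group by.
#' @return A `spectral_dataset` with one row per group, ordered by first
#'   appearance.
#' @export
average_consecutive_scans <- function(ds, by = "sample_id") {
  stopifnot(inherits(ds, "spectral_dataset"))
  missing_by <- setdiff(by, names(ds$meta))
  if (length(missing_by))
    stop("metadata key(s) not present: ", paste(missing_by, collapse = ", "),
         call. = FALSE)
  key <- do.call(paste, c(ds$meta[by], sep = "\r"))
  key <- factor(key, levels = unique(key))
  idx <- split(seq_along(key), key)
  A <- t(vapply(idx, function(i)
    colMeans(ds$absorbance[i, , drop = FALSE]),
    numeric(ncol(ds$absorbance))))
  first <- vapply(idx, `[`, integer(1), 1L)
  keep_cols <- setdiff(names(ds$meta), "scan_index")
  constant <- vapply(keep_cols, function(cn) {
    all(vapply(idx, function(i) length(unique(ds$meta[[cn]][i])) == 1L,
               logical(1)))
  }, logical(1))
  meta <- ds$meta[first, keep_cols[constant | keep_cols %in% by],
                  drop = FALSE]
  meta$n_scans <- lengths(idx)
  spectral_dataset(ds$wavelengths, A, meta)
}
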