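META_COLUMNS <- c("sample_id", "group_label", "temperature_C",
                  "concentration_mM", "replicate_id", "scan_index", "n_scans")

#' Read spectra from CSV
#'
#' Two dialects are supported. In the canonical *wide* dialect the leading
#' columns are metadata (any of `sample_id`, `group_label`, `temperature_C`,
#' `concentration_mM`, `replicate_id`, `scan_index`, plus any columns named
#' in `meta_cols`) and every remaining column is named by its wavelength in
#' nm with a `.` decimal separator (e.g. `1300`, `1300.5`, ...). The *long*
#' dialect has one row per (spectrum, wavelength) pair with columns
#' `wavelength_nm` and `absorbance`; rows belonging to one spectrum share a
#' `sample_id` and identical metadata.
#'
#' @param path path to a CSV file.
#' @param format `"wide"` or `"long"`.
#' @param meta_cols extra column names to treat as metadata (wide format),
#'   letting arbitrary spectrometer-export layouts be mapped.
#' @param declared_step optional uniform grid step (nm) to validate against.
#' @return A [spectral_dataset()].
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path, format = c("wide", "long"), meta_cols = NULL,
                         declared_step = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "wide") {
    known <- union(META_COLUMNS, meta_cols)
    is_meta <- names(df) %in% known
    wl <- suppressWarnings(as.numeric(names(df)[!is_meta]))
    if (!length(wl) || anyNA(wl))
      stop("format error: ", if (!length(wl)) "no wavelength columns found"
           else paste("non-numeric wavelength header(s):",
                      paste(names(df)[!is_meta][is.na(wl)], collapse = ", ")),
           call. = FALSE)
    spec <- df[!is_meta]
    bad <- which(!vapply(spec, is.numeric, logical(1)))
    if (length(bad)) {
      row <- which(is.na(suppressWarnings(as.numeric(spec[[bad[1]]]))))[1]
      stop("parse error: non-numeric absorbance in column '",
           names(spec)[bad[1]], "', row ", row, call. = FALSE)
    }
    ord <- order(wl)
    if (any(diff(wl[ord]) <= 0))
      stop("validation error: duplicated wavelength columns", call. = FALSE)
    spectral_dataset(wl[ord], as.matrix(spec)[, ord, drop = FALSE],
                     if (any(is_meta)) df[is_meta] else NULL,
                     declared_step = declared_step)
  } else {
    need <- c("sample_id", "wavelength_nm", "absorbance")
    if (!all(need %in% names(df)))
      stop("format error: long dialect requires columns ",
           paste(need, collapse = ", "), call. = FALSE)
    if (!is.numeric(df$absorbance)) {
      row <- which(is.na(suppressWarnings(as.numeric(df$absorbance))))[1]
      stop("parse error: non-numeric absorbance at row ", row, call. = FALSE)
    }
    sid <- factor(df$sample_id, levels = unique(df$sample_id))
    wl <- sort(unique(df$wavelength_nm))
    rows <- split(seq_len(nrow(df)), sid)
    A <- t(vapply(rows, function(i) {
      o <- order(df$wavelength_nm[i])
      if (!isTRUE(all.equal(df$wavelength_nm[i][o], wl)))
        stop("validation error: spectra do not share one wavelength grid",
             call. = FALSE)
      df$absorbance[i][o]
    }, numeric(length(wl))))
    mcols <- intersect(union(META_COLUMNS, meta_cols), names(df))
    meta <- df[vapply(rows, `[`, integer(1), 1L), mcols, drop = FALSE]
    spectral_dataset(wl, A, meta, declared_step = declared_step)
  }
}

#' Write spectra to CSV
#'
#' Writes the wide dialect by default (metadata columns first, then one
#' column per wavelength), or the long dialect. Round-tripping through
#' [read_spectra()] reproduces wavelengths and absorbance to better than
#' 1e-12.
#'
#' @param ds a [spectral_dataset()].
#' @param path output file path.
#' @param format `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ds, path, format = c("wide", "long")) {
  stopifnot(inherits(ds, "spectral_dataset"))
  format <- match.arg(format)
  if (format == "wide") {
    A <- as.data.frame(ds$absorbance)
    names(A) <- format(ds$wavelengths, digits = 15, trim = TRUE,
                       scientific = FALSE)
    out <- cbind(ds$meta, A)
  } else {
    p <- length(ds$wavelengths)
    n <- n_spectra(ds)
    out <- cbind(
      ds$meta[rep(seq_len(n), each = p), , drop = FALSE],
      data.frame(wavelength_nm = rep(ds$wavelengths, n),
                 absorbance = as.vector(t(ds$absorbance))))
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
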