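# bootstrap resampling matrix: n_boot x n of resample counts, so that group
# means over replicates are (counts %*% X) / n -- one BLAS call per group.
boot_counts <- function(n, n_boot) {
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  m <- matrix(0L, n_boot, n)
  dim(idx) <- c(n_boot, n)
  for (b in seq_len(n_boot)) m[b, ] <- tabulate(idx[b, ], nbins = n)
  m
}

#' Bootstrap percentile confidence interval for a group statistic
#'
#' Resamples the rows of `x` with replacement `n_boot` times, applies
#' `statistic` to each resample and returns the percentile bounds of the
#' replicate distribution. Rows are whole observations (here: whole
#' spectra); columns are never resampled.
#'
#' @param x numeric matrix, one row per observation.
#' @param statistic function mapping a matrix to a numeric vector; default
#'   column means.
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param level confidence level.
#' @param seed optional integer for reproducibility (caller RNG state is
#'   preserved).
#' @return A list with `lower`, `upper` (numeric vectors matching the
#'   statistic), and `replicates` (n_boot x length matrix). With a single
#'   row the interval has zero width and `degenerate = TRUE`.
#' @export
bootstrap_ci <- function(x, statistic = colMeans, n_boot = 1000,
                         level = 0.95, seed = NULL) {
  x <- as.matrix(x)
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  n <- nrow(x)
  est <- statistic(x)
  if (n == 1) {
    return(list(lower = est, upper = est,
                replicates = matrix(est, 1, length(est), byrow = TRUE),
                degenerate = TRUE))
  }
  with_seed(seed, {
    reps <- matrix(NA_real_, n_boot, length(est))
    for (b in seq_len(n_boot))
      reps[b, ] <- statistic(x[sample.int(n, n, replace = TRUE), ,
                               drop = FALSE])
    a <- (1 - level) / 2
    list(lower = apply(reps, 2, quantile, probs = a, names = FALSE),
         upper = apply(reps, 2, quantile, probs = 1 - a, names = FALSE),
         replicates = reps, degenerate = FALSE)
  })
}

percentile_bounds <- function(reps, level = 0.95) {
  a <- (1 - level) / 2
  q <- function(col, p) if (all(is.na(col))) NA_real_ else
    quantile(col, probs = p, names = FALSE)
  list(lower = apply(reps, 2, q, p = a),
       upper = apply(reps, 2, q, p = 1 - a))
}

#' Classic aquagram
#'
#' The classic aquagram value of a group at coordinate `c` is the group mean
#' of the MSC-pretreated, per-wavelength standardized absorbance at the
#' coordinate's center wavelength:
#' `A'_lambda = (A_lambda - mu_lambda) / sigma_lambda`,
#' where `mu_lambda` and `sigma_lambda` (sample SD, n - 1) are taken over
#' *all* spectra passed into the call -- the examined set is the whole set
#' being plotted. This whole-set standardization is what makes classic
#' values context dependent: removing groups from the call changes the
#' remaining groups' values (the instability the temperature-based aquagram
#' removes). A per-group alternative is exposed via `scope = "group"`.
#'
#' @param ds a [spectral_dataset()] containing the 1300--1600 nm window.
#' @param group_key metadata column defining the groups.
#' @param scheme a [wamac_scheme()]; values are read at the exact center
#'   wavelengths (nearest grid point within 1e-6 nm), not range averages.
#' @param n_boot bootstrap replicates for the 95% confidence limits;
#'   spectra are resampled with replacement within each group while the
#'   standardization context stays fixed.
#' @param seed integer seed for the bootstrap.
#' @param pretreatment `"msc"` (default) or `"snv"`.
#' @param msc_reference optional fixed reference spectrum for the MSC step
#'   (defaults to the mean spectrum of the examined set). Supplying a fixed
#'   reference makes values exactly invariant to per-spectrum affine
#'   distortions.
#' @param scope standardize over the whole examined `"set"` (default) or
#'   within each `"group"`.
#' @param level confidence level for the bootstrap interval.
#' @return An object of class `aquagram`; see [print.aquagram()].
#' @examples
#' m <- nir_water_model()
#' ds <- simulate_temperature_series(m, temps = c(25, 35, 45), seed = 1)
#' classic_aquagram(ds, "group_label", n_boot = 200, seed = 1)
#' @export
classic_aquagram <- function(ds, group_key = "group_label",
                             scheme = default_wamac_scheme(),
                             n_boot = 1000, seed = NULL,
                             pretreatment = c("msc", "snv"),
                             msc_reference = NULL,
                             scope = c("set", "group"), level = 0.95) {
  stopifnot(inherits(ds, "spectral_dataset"))
  pretreatment <- match.arg(pretreatment)
  scope <- match.arg(scope)
  if (!group_key %in% names(ds$meta))
    stop("group_key '", group_key, "' not in metadata", call. = FALSE)
  if (n_spectra(ds) < 2) stop("need >= 2 spectra", call. = FALSE)
  ds <- subset_wavelengths(ds, 1300, 1600)
  ds <- if (pretreatment == "msc") msc(ds, reference = msc_reference)
        else snv(ds)
  ci <- vapply(scheme$center_nm, function(w) wl_index(ds, w), integer(1))
  V <- ds$absorbance[, ci, drop = FALSE]          # n x 12, pretreated
  grp <- factor(ds$meta[[group_key]], levels = unique(ds$meta[[group_key]]))
  if (any(tabulate(grp) == 0)) stop("empty group", call. = FALSE)

  zscore <- function(M) {
    mu <- colMeans(M)
    sg <- apply(M, 2, sd)
    bad <- which(sg <= 0 | !is.finite(sg))
    if (length(bad))
      stop("degenerate-standardization error: zero spectral SD at ",
           paste(scheme$id[bad], collapse = ", "), call. = FALSE)
    sweep(sweep(M, 2, mu), 2, sg, "/")
  }
  if (scope == "set") {
    Z <- zscore(V)
  } else {
    Z <- V
    for (g in levels(grp)) Z[grp == g, ] <- zscore(V[grp == g, , drop = FALSE])
  }

  rows <- with_seed(seed, lapply(levels(grp), function(g) {
    Zg <- Z[grp == g, , drop = FALSE]
    val <- colMeans(Zg)
    ng <- nrow(Zg)
    if (ng == 1) {
      lo <- up <- val
    } else {
      reps <- boot_counts(ng, n_boot) %*% Zg / ng
      b <- percentile_bounds(reps, level)
      lo <- b$lower; up <- b$upper
    }
    data.frame(group = g, coordinate = scheme$id, center_nm = scheme$center_nm,
               value = val, lcl95 = pmin(lo, val), ucl95 = pmax(up, val),
               n = ng, conditioned = TRUE, mode = "classic",
               stringsAsFactors = FALSE)
  }))
  new_aquagram(do.call(rbind, rows), mode = "classic", scheme = scheme,
               units = "z", level = level)
}
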