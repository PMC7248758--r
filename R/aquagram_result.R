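new_aquagram <- function(df, mode, scheme, units, level) {
  rownames(df) <- NULL
  structure(df, class = c("aquagram", "data.frame"),
            aq_mode = mode, scheme = scheme, units = units, level = level)
}

#' Aquagram result objects
#'
#' [classic_aquagram()] and [temp_aquagram()] return an `aquagram`: a
#' `data.frame` with one row per (group, coordinate) and columns `group`,
#' `coordinate`, `center_nm`, `value` (z units for classic, degrees C for
#' temperature mode), `lcl95`, `ucl95`, `n`, `conditioned`, `mode`
#' (`"classic"`, `"absolute"` or `"delta"`). `lcl95 <= value <= ucl95`
#' holds for every reported cell. [coef.aquagram()] returns the values as a
#' groups x coordinates matrix; [write_aquagram()] exports the tidy table.
#'
#' @param x,object an `aquagram`.
#' @param ... unused.
#' @name aquagram
NULL

#' @rdname aquagram
#' @export
print.aquagram <- function(x, ...) {
  units <- attr(x, "units")
  cat("<aquagram> mode = ", attr(x, "aq_mode"), ", ",
      length(unique(x$group)), " group(s), values in ",
      if (units == "degC") "degrees C" else "z units", "\n", sep = "")
  df <- as.data.frame(x)
  df$value <- signif(df$value, 4)
  df$lcl95 <- signif(df$lcl95, 4)
  df$ucl95 <- signif(df$ucl95, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @rdname aquagram
#' @param which value mode to extract when both absolute and delta rows are
#'   present.
#' @export
coef.aquagram <- function(object, which = c("absolute", "delta",
                                            "classic"), ...) {
  which <- match.arg(which)
  df <- as.data.frame(object)
  if (which %in% df$mode) df <- df[df$mode == which, ]
  groups <- unique(df$group)
  coords <- unique(df$coordinate)
  m <- matrix(NA_real_, length(groups), length(coords),
              dimnames = list(groups, coords))
  m[cbind(match(df$group, groups), match(df$coordinate, coords))] <- df$value
  m
}

#' @rdname aquagram
#' @export
summary.aquagram <- function(object, ...) {
  df <- as.data.frame(object)
  cat("aquagram (", attr(object, "aq_mode"), " mode), ",
      length(unique(df$group)), " groups, level ",
      attr(object, "level"), "\n", sep = "")
  for (m in unique(df$mode)) {
    d <- df[df$mode == m, ]
    cat("mode '", m, "': value range [",
        signif(min(d$value, na.rm = TRUE), 4), ", ",
        signif(max(d$value, na.rm = TRUE), 4), "], ",
        sum(!d$conditioned), " ill-conditioned cell(s)\n", sep = "")
  }
  invisible(coef(object))
}

#' Read an exported aquagram back from CSV
#'
#' Rebuilds an `aquagram` object (for replotting) from a file written by
#' [write_aquagram()].
#'
#' @param path CSV file path.
#' @param scheme the [wamac_scheme()] the result was computed with.
#' @export
read_aquagram <- function(path, scheme = default_wamac_scheme()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "coordinate", "value", "lcl95", "ucl95", "n",
            "conditioned", "mode")
  if (!all(need %in% names(df)))
    stop("not an aquagram export: missing ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  mode <- if ("classic" %in% df$mode) "classic" else "temperature"
  new_aquagram(df, mode = mode, scheme = scheme,
               units = if (mode == "classic") "z" else "degC", level = 0.95)
}

#' Export an aquagram as tidy CSV
#'
#' Columns: group, coordinate, value, lcl95, ucl95, n, conditioned, mode.
#'
#' @param x an `aquagram`.
#' @param path output file path.
#' @export
write_aquagram <- function(x, path) {
  stopifnot(inherits(x, "aquagram"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
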