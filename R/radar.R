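# polar -> cartesian for axis k of K, clockwise from top, unit radius
axis_angle <- function(k, K) pi / 2 - (k - 1) * 2 * pi / K

radar_layout <- function(result, radial_range = NULL, pad = 0.1) {
  df <- as.data.frame(result)
  df <- df[df$mode == df$mode[1], ]          # one mode per chart
  coords <- unique(df$coordinate)
  if (is.null(radial_range)) {
    v <- c(df$value, df$lcl95, df$ucl95)
    v <- v[is.finite(v)]
    radial_range <- range(v) + c(-1, 1) * pad * diff(range(v))
    if (diff(radial_range) == 0) radial_range <- radial_range + c(-1, 1)
  }
  list(df = df, coords = coords, range = radial_range,
       groups = unique(df$group))
}

r_scale <- function(v, rng) (v - rng[1]) / (rng[2] - rng[1])

num <- function(x) sprintf("%.6g", x)

svg_polyline <- function(xy, col, dash, width = 1.5) {
  pts <- paste(num(xy[, 1]), num(xy[, 2]), sep = ",", collapse = " ")
  sprintf(paste0('<polygon points="%s" fill="none" stroke="%s" ',
                 'stroke-width="%s"%s/>'),
          pts, col, num(width),
          if (is.null(dash)) "" else
            sprintf(' stroke-dasharray="%s"', dash))
}

#' Render an aquagram radar chart
#'
#' Draws the 12 coordinates as radar axes ordered C01 to C12 clockwise from
#' the top. Per group, the solid line is the aquagram value, the dashed and
#' dotted lines are the upper and lower 95% confidence levels. The radial
#' axis is labelled in degrees Celsius (temperature mode) or z units
#' (classic mode). Output format follows the file extension: `.svg`
#' (canonical, deterministic text written directly) or `.png` (rendered
#' through the base-graphics device). Ill-conditioned coordinates are left
#' blank on their axes.
#'
#' @param result an `aquagram` (see [classic_aquagram()],
#'   [temp_aquagram()]). When both absolute and delta rows are present only
#'   the first mode is drawn; subset the result to choose.
#' @param out output file path ending in `.svg` or `.png`.
#' @param title chart title.
#' @param colors vector of group colours, recycled.
#' @param radial_range radial axis limits, default data range padded 10%.
#' @param radial_label radial axis label; default follows the mode.
#' @param width,height image size in pixels.
#' @return `out`, invisibly.
#' @export
render_aquagram <- function(result, out, title = "",
                            colors = palette.colors(10, "Tableau 10"),
                            radial_range = NULL, radial_label = NULL,
                            width = 640, height = 640) {
  stopifnot(inherits(result, "aquagram"))
  ext <- tolower(tools::file_ext(out))
  if (!ext %in% c("svg", "png"))
    stop("output extension must be .svg or .png", call. = FALSE)
  if (is.null(radial_label))
    radial_label <- if (attr(result, "units") == "degC")
      "temperature equivalent (°C)" else "standardized absorbance (z)"
  lay <- radar_layout(result, radial_range)
  if (ext == "png") {
    png(out, width = width, height = height)
    on.exit(dev.off())
    plot(result, title = title, colors = colors,
         radial_range = lay$range, radial_label = radial_label)
    return(invisible(out))
  }

  K <- length(lay$coords)
  cx <- width / 2; cy <- height / 2; R <- 0.38 * min(width, height)
  pt <- function(k, r) c(cx + R * r * cos(axis_angle(k, K)),
                         cy - R * r * sin(axis_angle(k, K)))
  ticks <- pretty(lay$range, n = 5)
  ticks <- ticks[ticks >= lay$range[1] & ticks <= lay$range[2]]
  L <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
                 width, height, width, height),
         sprintf('<rect width="%d" height="%d" fill="white"/>',
                 width, height),
         sprintf('<text x="%s" y="24" text-anchor="middle" font-size="16">%s</text>',
                 num(cx), title))
  for (tk in ticks) {                                   # grid rings + labels
    r <- r_scale(tk, lay$range)
    ring <- t(vapply(seq_len(K), pt, numeric(2), r = r))
    L <- c(L, svg_polyline(ring, "#cccccc", NULL, 0.7),
           sprintf('<text class="rtick" x="%s" y="%s" font-size="10" fill="#888888">%s</text>',
                   num(cx + 4), num(cy - R * r - 2), num(tk)))
  }
  for (k in seq_len(K)) {                               # axes + labels
    tip <- pt(k, 1.0); lab <- pt(k, 1.12)
    L <- c(L, sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#999999" stroke-width="0.7"/>',
                      num(cx), num(cy), num(tip[1]), num(tip[2])),
           sprintf('<text class="axis" x="%s" y="%s" text-anchor="middle" font-size="12">%s</text>',
                   num(lab[1]), num(lab[2]), lay$coords[k]))
  }
  for (gi in seq_along(lay$groups)) {                   # one trace per group
    g <- lay$groups[gi]
    col <- colors[(gi - 1) %% length(colors) + 1]
    dg <- lay$df[lay$df$group == g, ]
    dg <- dg[match(lay$coords, dg$coordinate), ]
    tr <- function(v) t(vapply(seq_len(K), function(k)
      pt(k, r_scale(v[k], lay$range)), numeric(2)))
    ok <- is.finite(dg$value)
    if (all(ok)) {
      L <- c(L, svg_polyline(tr(dg$value), col, NULL),
             svg_polyline(tr(dg$ucl95), col, "6,3", 1),
             svg_polyline(tr(dg$lcl95), col, "2,3", 1))
    } else {
      # broken trace: draw points only where conditioned
      xy <- tr(ifelse(ok, dg$value, lay$range[1]))
      for (k in which(ok))
        L <- c(L, sprintf('<circle cx="%s" cy="%s" r="3" fill="%s"/>',
                          num(xy[k, 1]), num(xy[k, 2]), col))
    }
    L <- c(L, sprintf('<text class="legend" x="16" y="%s" font-size="12" fill="%s">%s</text>',
                      num(20 + 16 * gi), col, g))
  }
  L <- c(L, sprintf('<text x="%s" y="%s" text-anchor="middle" font-size="12">%s</text>',
                    num(cx), num(height - 8), radial_label),
         "</svg>")
  writeLines(L, out)
  invisible(out)
}

#' @rdname aquagram
#' @param title,colors,radial_range,radial_label see [render_aquagram()].
#' @export
plot.aquagram <- function(x, title = "", colors = palette.colors(10,
                            "Tableau 10"), radial_range = NULL,
                          radial_label = NULL, ...) {
  lay <- radar_layout(x, radial_range)
  K <- length(lay$coords)
  op <- par(mar = c(2, 1, 3, 1)); on.exit(par(op))
  plot.new()
  plot.window(c(-1.35, 1.35), c(-1.35, 1.35), asp = 1)
  title(main = title)
  ticks <- pretty(lay$range, n = 5)
  ticks <- ticks[ticks >= lay$range[1] & ticks <= lay$range[2]]
  pxy <- function(k, r) c(r * cos(axis_angle(k, K)),
                          r * sin(axis_angle(k, K)))
  for (tk in ticks) {
    ring <- t(vapply(seq_len(K), pxy, numeric(2),
                     r = r_scale(tk, lay$range)))
    polygon(ring, border = "grey80")
    text(0.03, r_scale(tk, lay$range), num(tk), cex = 0.6, col = "grey40",
         adj = 0)
  }
  for (k in seq_len(K)) {
    tip <- pxy(k, 1); lab <- pxy(k, 1.2)
    segments(0, 0, tip[1], tip[2], col = "grey60")
    text(lab[1], lab[2], lay$coords[k], cex = 0.8)
  }
  for (gi in seq_along(lay$groups)) {
    col <- colors[(gi - 1) %% length(colors) + 1]
    dg <- lay$df[lay$df$group == lay$groups[gi], ]
    dg <- dg[match(lay$coords, dg$coordinate), ]
    tr <- function(v) {
      m <- t(vapply(seq_len(K), function(k)
        pxy(k, r_scale(v[k], lay$range)), numeric(2)))
      rbind(m, m[1, ])
    }
    if (all(is.finite(dg$value))) {
      lines(tr(dg$value), col = col, lwd = 2)
      lines(tr(dg$ucl95), col = col, lty = 2)
      lines(tr(dg$lcl95), col = col, lty = 3)
    } else {
      ok <- is.finite(dg$value)
      m <- tr(ifelse(ok, dg$value, lay$range[1]))
      points(m[which(ok), , drop = FALSE], col = col, pch = 16)
    }
  }
  legend("topleft", legend = lay$groups, bty = "n", cex = 0.8,
         col = colors[(seq_along(lay$groups) - 1) %% length(colors) + 1],
         lwd = 2)
  if (!is.null(radial_label)) graphics::mtext(radial_label, side = 1)
  invisible(x)
}
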