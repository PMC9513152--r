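#' Build a radar-chart specification of cohort index scores
#'
#' Axes are the 13 indexes in instrument order (grouped by attribute); one
#' polygon per level of the grouping variable plus an `all` polygon over the
#' whole cohort. Axis values are the per-group index means of
#' [mean_scores_by_group()] taken verbatim; a group whose index scores are
#' all missing gets an `NA` axis value, rendered as a gap.
#'
#' @param scorecards an `iit_scorecards` data.frame from [score_cohort()]
#' @param group_labels grouping vector aligned with the scorecards (e.g. the
#'   records' `research_type`); `NULL` for the `all` polygon only
#' @param instrument the instrument defining axis order
#' @return object of class `iit_radar`: list with `axes`, `groups` (matrix
#'   of axis values, one row per polygon), `sizes`, `range = c(0, 10)`
#' @export
build_radar <- function(scorecards, group_labels = NULL,
                        instrument = iit_instrument()) {
  if (nrow(scorecards) == 0) stop("no scorecards to plot")
  ids <- instrument$indexes$id
  all_means <- colMeans(as.matrix(scorecards[, ids, drop = FALSE]),
                        na.rm = TRUE)
  all_means[is.nan(all_means)] <- NA_real_
  if (is.null(group_labels)) {
    groups <- matrix(all_means, nrow = 1,
                     dimnames = list("all", ids))
    sizes <- c(all = nrow(scorecards))
  } else {
    g <- mean_scores_by_group(scorecards, group_labels, instrument)
    groups <- rbind(all = all_means, g$means)
    sizes <- c(all = nrow(scorecards), g$sizes)
  }
  structure(list(axes = ids, groups = groups, sizes = sizes,
                 range = c(0, 10)),
            class = "iit_radar")
}

#' Write a radar chart as a deterministic SVG file
#'
#' The SVG is generated textually with fixed-precision coordinates, so the
#' same specification always yields byte-identical output (golden-file
#' friendly). Missing axis values break the polygon into line segments.
#'
#' @param radar an [build_radar()] specification
#' @param path output file (`.svg`)
#' @param size canvas size in pixels
#' @return `path`, invisibly
#' @export
write_radar_svg <- function(radar, path, size = 520) {
  if (length(radar$groups) == 0 || nrow(radar$groups) == 0)
    stop("radar specification has no groups")
  p <- length(radar$axes)
  cx <- size / 2; cy <- size / 2; r_max <- size / 2 - 70
  ang <- pi / 2 - 2 * pi * (seq_len(p) - 1) / p   # start at 12 o'clock
  px <- function(v) sprintf("%.2f", v)
  pal <- c("#1b6ca8", "#d1495b", "#3e8e5a", "#8c6bb1", "#e0a81c",
           "#5c5c5c", "#17becf", "#9e5b30")
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    size, size, size, size),
    sprintf('<rect width="%d" height="%d" fill="white"/>', size, size))
  for (frac in seq(0.25, 1, by = 0.25)) {           # grid rings
    pts <- paste(px(cx + r_max * frac * cos(ang)),
                 px(cy - r_max * frac * sin(ang)), sep = ",",
                 collapse = " ")
    out <- c(out, sprintf(
      '<polygon points="%s" fill="none" stroke="#cccccc" stroke-width="1"/>',
      pts))
  }
  for (j in seq_len(p)) {                           # spokes + labels
    x2 <- cx + r_max * cos(ang[j]); y2 <- cy - r_max * sin(ang[j])
    out <- c(out, sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#cccccc" stroke-width="1"/>',
      px(cx), px(cy), px(x2), px(y2)))
    lx <- cx + (r_max + 12) * cos(ang[j])
    ly <- cy - (r_max + 12) * sin(ang[j])
    anchor <- if (abs(cos(ang[j])) < 0.3) "middle" else
      if (cos(ang[j]) > 0) "start" else "end"
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="9" font-family="sans-serif" text-anchor="%s">%s</text>',
      px(lx), px(ly), anchor, radar$axes[j]))
  }
  lo <- radar$range[1]; span <- diff(radar$range)
  for (gi in seq_len(nrow(radar$groups))) {
    v <- as.numeric(radar$groups[gi, ])
    col <- pal[(gi - 1) %% length(pal) + 1]
    rr <- r_max * (v - lo) / span
    xs <- cx + rr * cos(ang); ys <- cy - rr * sin(ang)
    ok <- !is.na(v)
    if (all(ok)) {
      out <- c(out, sprintf(
        '<polygon points="%s" fill="%s" fill-opacity="0.10" stroke="%s" stroke-width="2"/>',
        paste(px(xs), px(ys), sep = ",", collapse = " "), col, col))
    } else {
      runs <- rle(ok)                              # gaps at missing axes
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1
      for (ri in which(runs$values & runs$lengths > 1)) {
        seg <- starts[ri]:ends[ri]
        out <- c(out, sprintf(
          '<polyline points="%s" fill="none" stroke="%s" stroke-width="2"/>',
          paste(px(xs[seg]), px(ys[seg]), sep = ",", collapse = " "), col))
      }
    }
  }
  for (gi in seq_len(nrow(radar$groups))) {         # legend, input order
    col <- pal[(gi - 1) %% length(pal) + 1]
    y <- 16 + 14 * (gi - 1)
    out <- c(out,
      sprintf('<rect x="8" y="%d" width="10" height="10" fill="%s"/>',
              y - 9, col),
      sprintf('<text x="22" y="%d" font-size="10" font-family="sans-serif">%s (n=%d)</text>',
              y, rownames(radar$groups)[gi], radar$sizes[gi]))
  }
  out <- c(out, "</svg>")
  writeLines(out, path, sep = "\n")
  invisible(path)
}

#' Plot method for radar specifications
#'
#' Base-graphics rendering for interactive use; [write_radar_svg()] is the
#' deterministic file output.
#'
#' @param x an [build_radar()] specification
#' @param ... unused
#' @export
plot.iit_radar <- function(x, ...) {
  p <- length(x$axes)
  ang <- pi / 2 - 2 * pi * (seq_len(p) - 1) / p
  graphics::plot(NA, xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", ...)
  for (frac in seq(0.25, 1, 0.25))
    graphics::polygon(frac * cos(ang), frac * sin(ang), border = "grey80")
  graphics::segments(0, 0, cos(ang), sin(ang), col = "grey80")
  graphics::text(1.22 * cos(ang), 1.22 * sin(ang), x$axes, cex = 0.55)
  lo <- x$range[1]; span <- diff(x$range)
  for (gi in seq_len(nrow(x$groups))) {
    v <- (as.numeric(x$groups[gi, ]) - lo) / span
    graphics::polygon(v * cos(ang), v * sin(ang), border = gi + 1, lwd = 2)
  }
  graphics::legend("topleft", legend = rownames(x$groups),
                   col = seq_len(nrow(x$groups)) + 1, lwd = 2, bty = "n",
                   cex = 0.7)
  invisible(x)
}

#' Render a radar specification to SVG or PNG
#'
#' @param radar an [build_radar()] specification
#' @param path output path; `.svg` writes the deterministic SVG, `.png`
#'   renders the base-graphics plot
#' @export
render_radar <- function(radar, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") return(write_radar_svg(radar, path))
  if (ext == "png") {
    grDevices::png(path, width = 700, height = 700)
    on.exit(grDevices::dev.off())
    plot(radar)
    return(invisible(path))
  }
  stop("unsupported image format: ", ext)
}
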