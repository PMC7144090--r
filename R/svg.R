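DEFAULT_PALETTE <- c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
                     "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf")

num <- function(x) sprintf("%.3f", x)

svg_doc <- function(body, width, height) {
  paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="',
         width, '" height="', height, '" viewBox="0 0 ', width, ' ', height,
         '">\n', paste(body, collapse = "\n"), "\n</svg>\n")
}

svg_rect <- function(x, y, w, h, fill, id = NULL, opacity = 1) {
  paste0('<rect', if (!is.null(id)) paste0(' id="', id, '"'),
         ' x="', num(x), '" y="', num(y), '" width="', num(w),
         '" height="', num(h), '" fill="', fill,
         if (opacity < 1) paste0('" fill-opacity="', num(opacity)), '"/>')
}

svg_line <- function(x1, y1, x2, y2, stroke, width = 1) {
  paste0('<line x1="', num(x1), '" y1="', num(y1), '" x2="', num(x2),
         '" y2="', num(y2), '" stroke="', stroke, '" stroke-width="',
         num(width), '"/>')
}

svg_text <- function(x, y, text, size = 12, anchor = "start") {
  paste0('<text x="', num(x), '" y="', num(y), '" font-size="', size,
         '" font-family="sans-serif" text-anchor="', anchor, '">',
         text, '</text>')
}

category_colors <- function(categories, style = list()) {
  categories <- sort(unique(categories))
  colors <- style$colors %||% DEFAULT_PALETTE
  cols <- setNames(rep(colors, length.out = length(categories)), categories)
  if ("no-hit" %in% categories) cols["no-hit"] <- "#d0d0d0"
  cols
}

#' Render view statistics as a deterministic SVG document
#'
#' Produces byte-stable SVG 1.1 (fixed element order and number formatting)
#' for blob grids (with per-axis span histograms), kite summaries, cumulative
#' curves and snail plots.
#'
#' @param view_data A [bin_blob()], [kite_stats()], [cumulative_curves()] or
#'   [snail_stats()] object.
#' @param style Optional list: `colors` (palette), `width`, `height`.
#' @param path Optional output file.
#' @return The SVG document as a single string, invisibly when `path` is
#'   given.
#' @export
render_svg <- function(view_data, style = list(), path = NULL) {
  out <- if (inherits(view_data, "bin_grid")) svg_blob(view_data, style)
  else if (inherits(view_data, "kite_stats")) svg_kite(view_data, style)
  else if (inherits(view_data, "cumulative_curves")) svg_cumulative(view_data, style)
  else if (inherits(view_data, "snail_stats")) svg_snail(view_data, style)
  else stop("unsupported view data of class ", class(view_data)[1],
            call. = FALSE)
  if (!is.null(path)) {
    writeLines(out, path, sep = "")
    return(invisible(out))
  }
  out
}

plot_frame <- function(size, margin, hist) {
  list(x0 = margin, y0 = margin + hist, side = size - 2 * margin - hist)
}

svg_blob <- function(grid, style) {
  size <- style$width %||% 760
  margin <- 60
  hist_h <- 80
  fr <- plot_frame(size, margin, hist_h)
  res <- grid$resolution
  cell <- fr$side / res
  cols <- category_colors(grid$cells$category, style)
  body <- character(0)
  body <- c(body, svg_rect(fr$x0, fr$y0, fr$side, fr$side, "#ffffff"))
  # axis histograms: span per column (top) and per row (right)
  xspan <- tapply(grid$cells$span, factor(grid$cells$ix, levels = 0:(res - 1)),
                  sum)
  yspan <- tapply(grid$cells$span, factor(grid$cells$iy, levels = 0:(res - 1)),
                  sum)
  xspan[is.na(xspan)] <- 0
  yspan[is.na(yspan)] <- 0
  mx <- max(xspan, 1)
  my <- max(yspan, 1)
  for (i in seq_len(res)) {
    if (xspan[i] > 0) {
      h <- hist_h * xspan[i] / mx
      body <- c(body, svg_rect(fr$x0 + (i - 1) * cell, fr$y0 - h,
                               cell * 0.9, h, "#9e9e9e"))
    }
    if (yspan[i] > 0) {
      w <- hist_h * yspan[i] / my
      body <- c(body, svg_rect(fr$x0 + fr$side + 2,
                               fr$y0 + fr$side - i * cell, w, cell * 0.9,
                               "#9e9e9e"))
    }
  }
  cells <- grid$cells
  for (r in seq_len(nrow(cells))) {
    side <- cells$side[r] * cell
    cx <- fr$x0 + cells$ix[r] * cell + cell / 2
    cy <- fr$y0 + fr$side - cells$iy[r] * cell - cell / 2
    body <- c(body, svg_rect(cx - side / 2, cy - side / 2, side, side,
                             cols[[cells$category[r]]],
                             id = paste0("cell-", cells$ix[r], "-",
                                         cells$iy[r], "-", r)))
  }
  body <- c(body,
            svg_line(fr$x0, fr$y0 + fr$side, fr$x0 + fr$side,
                     fr$y0 + fr$side, "#000000"),
            svg_line(fr$x0, fr$y0, fr$x0, fr$y0 + fr$side, "#000000"),
            svg_text(fr$x0 + fr$side / 2, size - 12,
                     grid$x_axis$field_id, anchor = "middle"),
            svg_text(16, fr$y0 + fr$side / 2, grid$y_axis$field_id))
  k <- 0
  for (cat in names(cols)) {
    body <- c(body, svg_rect(fr$x0 + fr$side + 8, fr$y0 + fr$side - 14 * k - 10,
                             10, 10, cols[[cat]]),
              svg_text(fr$x0 + fr$side + 22, fr$y0 + fr$side - 14 * k,
                       cat, size = 10))
    k <- k + 1
  }
  svg_doc(body, size, size)
}

to_px <- function(v, bounds, x0, side, flip = FALSE) {
  u <- (v - bounds[1]) / (bounds[2] - bounds[1])
  if (flip) x0 + side - u * side else x0 + u * side
}

svg_kite <- function(ks, style) {
  size <- style$width %||% 760
  margin <- 60
  fr <- plot_frame(size, margin, 0)
  bx <- axis_bounds(ks$x_axis)
  by <- axis_bounds(ks$y_axis)
  cols <- category_colors(names(ks$categories), style)
  body <- c(svg_rect(fr$x0, fr$y0, fr$side, fr$side, "#ffffff"))
  for (cat in sort(names(ks$categories))) {
    s <- ks$categories[[cat]]
    col <- cols[[cat]]
    cxm <- to_px(s$median[["x"]], bx, fr$x0, fr$side)
    cym <- to_px(s$median[["y"]], by, fr$y0, fr$side, flip = TRUE)
    dx <- 2 * s$sd[["x"]] / diff(bx) * fr$side
    dy <- 2 * s$sd[["y"]] / diff(by) * fr$side
    # regression slope converted to (y-down) pixel space sets the kite angle
    ang <- atan(-s$slope * diff(bx) / diff(by))
    body <- c(body,
              svg_line(cxm - dx * cos(ang), cym - dx * sin(ang),
                       cxm + dx * cos(ang), cym + dx * sin(ang), col, 2),
              svg_line(cxm + dy * sin(ang), cym - dy * cos(ang),
                       cxm - dy * sin(ang), cym + dy * cos(ang), col, 2),
              svg_text(cxm + 4, cym - 4, cat, size = 10))
  }
  body <- c(body,
            svg_line(fr$x0, fr$y0 + fr$side, fr$x0 + fr$side, fr$y0 + fr$side,
                     "#000000"),
            svg_line(fr$x0, fr$y0, fr$x0, fr$y0 + fr$side, "#000000"),
            svg_text(fr$x0 + fr$side / 2, size - 12, ks$x_axis$field_id,
                     anchor = "middle"),
            svg_text(16, fr$y0 + fr$side / 2, ks$y_axis$field_id))
  svg_doc(body, size, size)
}

svg_polyline <- function(xs, ys, stroke, width = 2) {
  pts <- paste(paste0(num(xs), ",", num(ys)), collapse = " ")
  paste0('<polyline points="', pts, '" fill="none" stroke="', stroke,
         '" stroke-width="', num(width), '"/>')
}

svg_cumulative <- function(cc, style) {
  size <- style$width %||% 760
  margin <- 60
  fr <- plot_frame(size, margin, 0)
  nmax <- max(cc$overall$k)
  body <- c(svg_rect(fr$x0, fr$y0, fr$side, fr$side, "#ffffff"))
  px <- function(k) fr$x0 + k / nmax * fr$side
  py <- function(s) fr$y0 + fr$side - s / cc$total_span * fr$side
  body <- c(body, svg_polyline(px(c(0, cc$overall$k)),
                               py(c(0, cc$overall$span)), "#000000", 2.5))
  cols <- category_colors(names(cc$curves), style)
  for (cat in names(cc$curves)) {
    cv <- cc$curves[[cat]]
    body <- c(body, svg_polyline(px(c(0, cv$k)), py(c(0, cv$span)),
                                 cols[[cat]]))
  }
  body <- c(body,
            svg_line(fr$x0, fr$y0 + fr$side, fr$x0 + fr$side, fr$y0 + fr$side,
                     "#000000"),
            svg_line(fr$x0, fr$y0, fr$x0, fr$y0 + fr$side, "#000000"),
            svg_text(fr$x0 + fr$side / 2, size - 12, "contigs (largest first)",
                     anchor = "middle"),
            svg_text(16, fr$y0 + fr$side / 2, "cumulative span"))
  svg_doc(body, size, size)
}

svg_snail <- function(sn, style) {
  size <- style$width %||% 760
  cx <- size / 2
  cy <- size / 2
  r_out <- size / 2 - 60
  r_in <- r_out * 0.25
  body <- character(0)
  segs <- sn$segments
  scale_len <- function(l) r_in + (r_out - r_in) * l / sn$longest
  step <- max(1L, segs %/% 720L)
  shown <- seq(1L, segs, by = step)
  for (s in shown) {
    a <- 2 * pi * s / segs - pi / 2
    r <- scale_len(sn$segment_length[s])
    body <- c(body, svg_line(cx + r_in * cos(a), cy + r_in * sin(a),
                             cx + r * cos(a), cy + r * sin(a), "#de4f38",
                             width = 720 / length(shown)))
  }
  for (frac in c(0.5, 0.9)) {
    a <- 2 * pi * frac - pi / 2
    nx <- if (frac == 0.5) sn$n50 else sn$n90
    r <- scale_len(nx)
    body <- c(body, svg_line(cx, cy, cx + r_out * cos(a), cy + r_out * sin(a),
                             "#666666", 1),
              svg_text(cx + (r_out + 6) * cos(a), cy + (r_out + 6) * sin(a),
                       paste0("N", frac * 100, "=", nx), size = 10))
  }
  body <- c(body,
            svg_text(cx, cy - 10, paste0("span ", sn$span), anchor = "middle"),
            svg_text(cx, cy + 6, paste0(sn$count, " contigs"),
                     anchor = "middle"),
            svg_text(cx, cy + 22, sprintf("GC %.3f", sn$gc),
                     anchor = "middle"))
  svg_doc(body, size, size)
}
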