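#' Axis specification for plot-statistic computations
#'
#' @param field_id Field plotted on the axis.
#' @param transform `"linear"` or `"log10"`.
#' @param domain `[lo, hi]` in data units (`lo < hi`; positive after clamping
#'   when `transform = "log10"`).
#' @param clamp_min Values below this are substituted by it before the
#'   transform (the conventional coverage floor is 0.01).
#' @return List of class `axis_spec`.
#' @export
axis_spec <- function(field_id, transform = c("linear", "log10"),
                      domain, clamp_min = NULL) {
  transform <- match.arg(transform)
  domain <- as.numeric(domain)
  if (length(domain) != 2L || domain[1] >= domain[2]) {
    stop("axis domain must satisfy lo < hi", call. = FALSE)
  }
  if (transform == "log10") {
    lo <- if (is.null(clamp_min)) domain[1] else max(domain[1], clamp_min)
    if (lo <= 0) stop("log10 axis requires a positive domain after clamping",
                      call. = FALSE)
  }
  structure(list(field_id = field_id, transform = transform,
                 domain = domain, clamp_min = clamp_min),
            class = "axis_spec")
}

transform_values <- function(values, axis) {
  if (!is.null(axis$clamp_min)) values <- pmax(values, axis$clamp_min)
  if (axis$transform == "log10") log10(values) else values
}

axis_bounds <- function(axis) {
  transform_values(axis$domain, axis)
}

#' Default axis for a field
#'
#' GC-like proportions get a linear [0, 1] axis; coverage fields a log10 axis
#' with a 0.01 floor; anything else a linear axis over the observed range.
#'
#' @param dataset A `blobdir`.
#' @param field_id Variable field id.
#' @return An [axis_spec()].
#' @export
default_axis <- function(dataset, field_id) {
  rng <- dataset$fields[[field_id]]$meta$range
  if (is.null(rng)) stop("no range for field '", field_id, "'", call. = FALSE)
  if (grepl("^gc$|_gc$|^n$", field_id)) {
    return(axis_spec(field_id, "linear", c(0, 1)))
  }
  if (grepl("cov", field_id)) {
    hi <- max(rng[2], 0.1)
    return(axis_spec(field_id, "log10", c(0.01, hi * 1.000001),
                     clamp_min = 0.01))
  }
  hi <- if (rng[2] > rng[1]) rng[2] else rng[1] + 1
  axis_spec(field_id, "linear", c(rng[1], hi * (1 + 1e-9)))
}

#' Map values to bin indices along one axis
#'
#' `floor((t(v) - lo) / (hi - lo) * resolution)` on clamped, transformed
#' values, with out-of-domain values clamped to the edge bins and the upper
#' domain edge assigned to bin `resolution - 1`.
#'
#' @param value Numeric vector.
#' @param axis An [axis_spec()].
#' @param resolution Number of divisions (>= 1).
#' @return Integer bin indices in `[0, resolution - 1]`.
#' @export
assign_bin <- function(value, axis, resolution = 30L) {
  stopifnot(resolution >= 1L)
  b <- axis_bounds(axis)
  v <- transform_values(value, axis)
  idx <- floor((v - b[1]) / (b[2] - b[1]) * resolution)
  pmax(0L, pmin(as.integer(resolution) - 1L, as.integer(idx)))
}

hex_cells <- function(x, y, resolution) {
  # nearest centre on an offset hexagonal lattice (unit square coordinates)
  dx <- 1 / resolution
  dy <- dx * sqrt(3) / 2
  r0 <- floor(y / dy)
  best_ix <- integer(length(x))
  best_iy <- integer(length(x))
  best_d <- rep(Inf, length(x))
  for (r in list(r0, r0 + 1)) {
    off <- (r %% 2) * 0.5
    c_ <- round(x / dx - off)
    cx <- (c_ + off) * dx
    cy <- r * dy
    d <- (x - cx)^2 + (y - cy)^2
    upd <- d < best_d
    best_ix[upd] <- c_[upd]
    best_iy[upd] <- r[upd]
    best_d[upd] <- d[upd]
  }
  list(ix = best_ix, iy = best_iy)
}

grid_cells <- function(dataset, x_axis, y_axis, resolution, shape) {
  x <- variable_values(dataset, x_axis$field_id)
  y <- variable_values(dataset, y_axis$field_id)
  if (shape == "square") {
    list(ix = assign_bin(x, x_axis, resolution),
         iy = assign_bin(y, y_axis, resolution))
  } else {
    bx <- axis_bounds(x_axis)
    by <- axis_bounds(y_axis)
    ux <- pmin(1, pmax(0, (transform_values(x, x_axis) - bx[1]) / (bx[2] - bx[1])))
    uy <- pmin(1, pmax(0, (transform_values(y, y_axis) - by[1]) / (by[2] - by[1])))
    hex_cells(ux, uy, resolution)
  }
}

scale_fun <- function(scale) {
  switch(scale,
         sqrt = function(s) sqrt(s),
         linear = function(s) s,
         log = function(s) log10(1 + s),
         stop("unknown scale: ", scale, call. = FALSE))
}

#' Square- (or hex-) binned blob-plot grid
#'
#' Divides the x/y plane into an evenly spaced grid and, per cell and
#' category, sums the spans (contig lengths) and counts of the contigs that
#' fall there. Rendered square sides are `scale(span) / scale(max cell
#' span)`, so the largest cell fills its cell exactly; within a cell,
#' categories are drawn in descending span order so every category stays
#' visible as concentric squares.
#'
#' @param dataset A `blobdir` with a `length` field.
#' @param x_field,y_field Variable field ids (default GC proportion against
#'   the first coverage field).
#' @param cat_field Category field id used for colouring (default: first
#'   category field).
#' @param resolution Divisions per axis (default 30).
#' @param scale Side-scaling function: `"sqrt"` (default), `"linear"` or
#'   `"log"`.
#' @param x_axis,y_axis Optional [axis_spec()] overrides.
#' @param shape `"square"` (default) or `"hex"`.
#' @return An object of class `bin_grid`.
#' @export
bin_blob <- function(dataset, x_field = "gc", y_field = NULL, cat_field = NULL,
                     resolution = 30L, scale = c("sqrt", "linear", "log"),
                     x_axis = NULL, y_axis = NULL,
                     shape = c("square", "hex")) {
  scale <- match.arg(scale)
  shape <- match.arg(shape)
  if (is.null(y_field)) {
    covs <- names(Filter(function(f) f$meta$type == "variable" &&
                           grepl("cov", f$meta$id), dataset$fields))
    if (!length(covs)) stop("no coverage field to plot", call. = FALSE)
    y_field <- covs[[1L]]
  }
  if (is.null(cat_field)) {
    cats <- names(Filter(function(f) f$meta$type == "category", dataset$fields))
    cat_field <- if (length(cats)) cats[[1L]] else NULL
  }
  if (is.null(x_axis)) x_axis <- default_axis(dataset, x_field)
  if (is.null(y_axis)) y_axis <- default_axis(dataset, y_field)
  cells_idx <- grid_cells(dataset, x_axis, y_axis, resolution, shape)
  lengths <- variable_values(dataset, "length")
  category <- if (is.null(cat_field)) rep("all", length(lengths))
              else field_values(dataset, cat_field)
  key <- paste(cells_idx$ix, cells_idx$iy, category, sep = "\r")
  span <- tapply(lengths, key, sum)
  count <- tapply(lengths, key, length)
  parts <- strsplit(names(span), "\r", fixed = TRUE)
  cells <- data.frame(
    ix = as.integer(vapply(parts, `[[`, character(1), 1L)),
    iy = as.integer(vapply(parts, `[[`, character(1), 2L)),
    category = vapply(parts, `[[`, character(1), 3L),
    span = as.numeric(span), count = as.integer(count),
    stringsAsFactors = FALSE)
  cell_total <- tapply(cells$span, paste(cells$ix, cells$iy), sum)
  max_span <- max(cell_total)
  sf <- scale_fun(scale)
  cells$side <- sf(cells$span) / sf(max_span)
  cells <- cells[order(cells$ix, cells$iy, -cells$span), , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(resolution = as.integer(resolution), shape = shape,
                 scale = scale, x_axis = x_axis, y_axis = y_axis,
                 cat_field = cat_field, cells = cells,
                 max_cell_span = as.numeric(max_span),
                 total_span = sum(lengths),
                 contig_cells = cells_idx),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("bin_grid: ", x$resolution, "x", x$resolution, " (", x$shape, "), ",
      nrow(x$cells), " occupied cell entries, total span ",
      format(x$total_span, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Identifiers falling in one grid cell
#'
#' @param grid A [bin_blob()] result.
#' @param ix,iy Cell indices.
#' @param dataset The dataset the grid was computed from.
#' @return Character vector of identifiers, in dataset order.
#' @export
select_bin <- function(grid, ix, iy, dataset) {
  res <- grid$resolution
  if (grid$shape == "square" &&
      (ix < 0 || ix >= res || iy < 0 || iy >= res)) {
    stop("cell (", ix, ", ", iy, ") outside grid", call. = FALSE)
  }
  hit <- grid$contig_cells$ix == ix & grid$contig_cells$iy == iy
  dataset$identifiers[hit]
}

weighted_mean_sd <- function(v, w) {
  mu <- sum(w * v) / sum(w)
  list(mean = mu, sd = sqrt(sum(w * (v - mu)^2) / sum(w)))
}

weighted_median <- function(v, w) {
  o <- order(v)
  v <- v[o]
  w <- w[o]
  cw <- cumsum(w)
  v[which(cw >= sum(w) / 2)[1L]]
}

#' Per-category kite statistics
#'
#' For each category, computes in transformed plot coordinates (so angles
#' match what is drawn on a log-coverage axis), with contig lengths as
#' weights: the weighted mean and standard deviation on each axis, the
#' extents (mean +/- 2 sd), the weighted median point and the slope and
#' intercept of the weighted least-squares regression of y on x. A
#' single-member category reports sd 0 and, by convention, slope 0 (as does
#' any category with zero x variance).
#'
#' @inheritParams bin_blob
#' @return Object of class `kite_stats`: a named list per category with
#'   elements `mean`, `sd`, `extent_x`, `extent_y`, `median`, `slope`,
#'   `intercept`, `span`, `count`.
#' @export
kite_stats <- function(dataset, x_field = "gc", y_field = NULL,
                       cat_field = NULL, x_axis = NULL, y_axis = NULL) {
  if (is.null(y_field)) {
    covs <- names(Filter(function(f) f$meta$type == "variable" &&
                           grepl("cov", f$meta$id), dataset$fields))
    if (!length(covs)) stop("no coverage field to plot", call. = FALSE)
    y_field <- covs[[1L]]
  }
  if (is.null(cat_field)) {
    cats <- names(Filter(function(f) f$meta$type == "category", dataset$fields))
    cat_field <- if (length(cats)) cats[[1L]] else NULL
  }
  if (is.null(x_axis)) x_axis <- default_axis(dataset, x_field)
  if (is.null(y_axis)) y_axis <- default_axis(dataset, y_field)
  x <- transform_values(variable_values(dataset, x_field), x_axis)
  y <- transform_values(variable_values(dataset, y_field), y_axis)
  w <- variable_values(dataset, "length")
  if (sum(w) <= 0) stop("zero total weight", call. = FALSE)
  category <- if (is.null(cat_field)) rep("all", length(w))
              else field_values(dataset, cat_field)
  out <- lapply(split(seq_along(w), category), function(idx) {
    xs <- x[idx]; ys <- y[idx]; ws <- w[idx]
    mx <- weighted_mean_sd(xs, ws)
    my <- weighted_mean_sd(ys, ws)
    den <- sum(ws * (xs - mx$mean)^2)
    slope <- if (length(idx) < 2L || den == 0) 0 else
      sum(ws * (xs - mx$mean) * (ys - my$mean)) / den
    list(mean = c(x = mx$mean, y = my$mean),
         sd = c(x = mx$sd, y = my$sd),
         extent_x = c(mx$mean - 2 * mx$sd, mx$mean + 2 * mx$sd),
         extent_y = c(my$mean - 2 * my$sd, my$mean + 2 * my$sd),
         median = c(x = weighted_median(xs, ws), y = weighted_median(ys, ws)),
         slope = slope,
         intercept = my$mean - slope * mx$mean,
         span = sum(ws), count = length(idx))
  })
  structure(list(categories = out, x_axis = x_axis, y_axis = y_axis,
                 cat_field = cat_field),
            class = "kite_stats")
}

#' Cumulative span curves
#'
#' Within the whole assembly and within each category, contig lengths are
#' sorted in descending order and accumulated, giving the span represented by
#' the k largest contigs. Stacking order is by descending category span.
#'
#' @param dataset A `blobdir` with a `length` field.
#' @param cat_field Optional category field for per-category curves.
#' @return Object of class `cumulative_curves`: `overall` (data frame `k`,
#'   `span`) and `curves` (named list of the same per category, in stacking
#'   order).
#' @export
cumulative_curves <- function(dataset, cat_field = NULL) {
  lengths <- variable_values(dataset, "length")
  curve <- function(l) {
    l <- sort(l, decreasing = TRUE)
    data.frame(k = seq_along(l), span = cumsum(l))
  }
  curves <- list()
  if (!is.null(cat_field)) {
    groups <- split(lengths, field_values(dataset, cat_field))
    groups <- groups[order(-vapply(groups, sum, numeric(1)))]
    curves <- lapply(groups, curve)
  }
  structure(list(overall = curve(lengths), curves = curves,
                 total_span = sum(lengths), cat_field = cat_field),
            class = "cumulative_curves")
}

#' Nx assembly statistic
#'
#' The length of the contig at which the descending-sorted cumulative span
#' first reaches `fraction` of the total span (N50 at 0.5, N90 at 0.9).
#'
#' @param lengths Non-empty numeric vector of contig lengths.
#' @param fraction Fraction of total span in (0, 1).
#' @return The Nx length.
#' @export
nx_statistic <- function(lengths, fraction = 0.5) {
  if (!length(lengths)) stop("empty length vector", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)",
                                           call. = FALSE)
  l <- sort(lengths, decreasing = TRUE)
  l[which(cumsum(l) >= fraction * sum(l))[1L]]
}

#' Snail-plot statistics
#'
#' Scalar assembly statistics (span, count, longest, N50, N90 and
#' length-weighted GC / AT / N proportions) plus, along the
#' descending-length-sorted concatenation of the assembly divided into
#' `segments` equal cumulative slices: the scaffold length at each slice
#' boundary and the min / length-weighted mean / max GC of the contigs
#' overlapping each slice. BUSCO lineage totals are copied from any BUSCO
#' fields present.
#'
#' @param dataset A `blobdir` with `length` and `gc` fields.
#' @param segments Number of cumulative slices (default 1000).
#' @return Object of class `snail_stats`.
#' @export
snail_stats <- function(dataset, segments = 1000L) {
  lengths <- variable_values(dataset, "length")
  gc <- variable_values(dataset, "gc")
  nprop <- variable_values(dataset, "n", required = FALSE)
  if (is.null(nprop)) nprop <- numeric(length(lengths))
  o <- order(lengths, decreasing = TRUE)
  l <- lengths[o]
  g <- gc[o]
  span <- sum(l)
  cum <- cumsum(l)
  pos <- span * seq_len(segments) / segments
  idx <- findInterval(pos, cum, left.open = TRUE) + 1L
  idx <- pmin(idx, length(l))
  seg_gc <- lapply(seq_len(segments), function(s) {
    lo <- if (s == 1L) 0 else pos[s - 1L]
    first <- findInterval(lo, cum, left.open = TRUE) + 1L
    last <- idx[s]
    win <- first:last
    c(min = min(g[win]),
      mean = sum(g[win] * l[win]) / sum(l[win]),
      max = max(g[win]))
  })
  seg_gc <- do.call(rbind, seg_gc)
  mean_gc <- sum(gc * lengths) / span
  mean_n <- sum(nprop * lengths) / span
  busco_fields <- names(Filter(function(f) !is.null(f$meta$busco_total),
                               dataset$fields))
  busco <- lapply(setNames(busco_fields, sub("_busco$", "", busco_fields)),
                  function(fid) {
                    m <- dataset$fields[[fid]]$meta
                    list(total = m$busco_total,
                         counts = unlist(m$busco_counts))
                  })
  structure(list(span = span, count = length(l), longest = max(l),
                 n50 = nx_statistic(l, 0.5), n90 = nx_statistic(l, 0.9),
                 gc = mean_gc, at = 1 - mean_gc, n = mean_n,
                 segment_length = l[idx], segment_gc = seg_gc,
                 segments = as.integer(segments), busco = busco),
            class = "snail_stats")
}

#' @export
print.snail_stats <- function(x, ...) {
  cat("assembly: span", format(x$span, big.mark = ","),
      "count", x$count, "\n")
  cat("longest", x$longest, " N50", x$n50, " N90", x$n90, "\n")
  cat(sprintf("GC %.4f  AT %.4f  N %.4f\n", x$gc, x$at, x$n))
  invisible(x)
}

get_busco_field <- function(dataset, lineage) {
  fid <- paste0(lineage, "_busco")
  f <- dataset$fields[[fid]]
  if (is.null(f)) stop("unknown BUSCO lineage: ", lineage, call. = FALSE)
  f
}

#' Filter-aware BUSCO summary
#'
#' Recomputes the per-status counts under an inclusion mask: a BUSCO id is
#' Duplicated when two or more retained contigs carry it complete, Complete
#' when exactly one does, Fragmented when no retained contig carries it
#' complete but one carries a fragment, Missing otherwise. Counts always sum
#' to the lineage total.
#'
#' @param dataset A `blobdir` with a BUSCO field (see [add_busco_field()]).
#' @param mask Logical inclusion vector (default: all retained).
#' @param lineage BUSCO lineage id.
#' @return Named integer vector over Complete, Duplicated, Fragmented,
#'   Missing.
#' @export
busco_summary <- function(dataset, mask = NULL, lineage) {
  f <- get_busco_field(dataset, lineage)
  if (is.null(mask)) mask <- rep(TRUE, length(dataset$identifiers))
  all_ids <- as.character(unlist(f$meta$busco_ids))
  complete_carriers <- integer(0)
  fragmented <- character(0)
  for (i in which(mask)) {
    for (rec in f$values[[i]]) {
      b <- rec[[1L]]
      st <- rec[[2L]]
      if (st %in% c("Complete", "Duplicated")) {
        prev <- if (b %in% names(complete_carriers)) complete_carriers[[b]] else 0L
        complete_carriers[b] <- prev + 1L
      } else if (st == "Fragmented") {
        fragmented <- c(fragmented, b)
      }
    }
  }
  status <- vapply(all_ids, function(b) {
    carriers <- complete_carriers[b]
    if (!is.na(carriers) && carriers >= 2L) "Duplicated"
    else if (!is.na(carriers) && carriers == 1L) "Complete"
    else if (b %in% fragmented) "Fragmented"
    else "Missing"
  }, character(1))
  counts <- vapply(BUSCO_STATUSES, function(s) sum(status == s), integer(1))
  stopifnot(sum(counts) == length(all_ids))
  counts
}

#' Contigs carrying a BUSCO of a given status
#'
#' @param dataset A `blobdir` with a BUSCO field.
#' @param lineage BUSCO lineage id.
#' @param status One of Complete, Duplicated, Fragmented, Missing.
#' @return Identifiers carrying at least one such record, in dataset order
#'   (always empty for Missing: no contig carries a missing BUSCO).
#' @export
busco_category_ids <- function(dataset, lineage, status) {
  if (!status %in% BUSCO_STATUSES) {
    stop("unknown BUSCO status: ", status, call. = FALSE)
  }
  f <- get_busco_field(dataset, lineage)
  carries <- vapply(f$values, function(recs) {
    any(vapply(recs, function(r) identical(r[[2L]], status), logical(1)))
  }, logical(1))
  dataset$identifiers[carries]
}

#' Similarity-hit layout along one contig
#'
#' Returns the stored hits for a contig in input order, with taxids resolved
#' to taxon names at the requested rank via the stored per-rank assignments.
#'
#' @param dataset A `blobdir` carrying taxonomy fields
#'   (see [add_taxonomy_fields()]).
#' @param contig_id Contig identifier.
#' @param rank Taxonomic rank for hit labels (default `"phylum"`).
#' @param taxrule Taxrule prefix of the stored fields (default: the
#'   dataset's recorded taxrule).
#' @return Data frame with columns `qstart`, `qend`, `taxon`, `bitscore`.
#' @export
contig_hit_layout <- function(dataset, contig_id, rank = "phylum",
                              taxrule = NULL) {
  i <- match(contig_id, dataset$identifiers)
  if (is.na(i)) stop("unknown contig: ", contig_id, call. = FALSE)
  if (is.null(taxrule)) taxrule <- dataset$meta$taxrule %||% "bestsum"
  pos_field <- dataset$fields[[paste0(taxrule, "_positions")]]
  if (is.null(pos_field)) stop("no hit-position field present", call. = FALSE)
  hits_field <- dataset$fields[[paste0(taxrule, "_", rank, "_hits")]]
  rows <- pos_field$values[[i]]
  if (!length(rows)) {
    return(data.frame(qstart = numeric(0), qend = numeric(0),
                      taxon = character(0), bitscore = numeric(0),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, rows)
  taxa <- if (!is.null(hits_field)) {
    hits_field$keys[unlist(hits_field$values[[i]]) + 1L]
  } else {
    paste0("taxid-", m[, 3L])
  }
  len <- variable_values(dataset, "length")[i]
  if (any(m[, 2L] > len, na.rm = TRUE)) {
    stop("hit span exceeds contig length on ", contig_id, call. = FALSE)
  }
  data.frame(qstart = m[, 1L], qend = m[, 2L], taxon = taxa,
             bitscore = m[, 4L], stringsAsFactors = FALSE)
}

#' Default presentation for a dataset of a given size
#'
#' Below 100,000 contigs individual scaled circles are a reasonable
#' presentation; above it only binned views are exposed; above 1,000,000
#' contigs the default view additionally filters out `no-hit` contigs.
#'
#' @param n_contigs Number of contigs.
#' @param circle_threshold,nohit_threshold The two thresholds.
#' @return List with `mode` (`"circle"` or `"binned"`) and `filter_nohit`.
#' @export
view_defaults <- function(n_contigs, circle_threshold = 100000L,
                          nohit_threshold = 1000000L) {
  list(mode = if (n_contigs < circle_threshold) "circle" else "binned",
       filter_nohit = n_contigs > nohit_threshold)
}
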