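test_that("bin assignment clamps and hits the documented examples", {
  gc_axis <- axis_spec("gc", "linear", c(0, 1))
  expect_equal(assign_bin(0.5, gc_axis, 30), 15L)
  expect_equal(assign_bin(1.0, gc_axis, 30), 29L)  # upper-edge clamp
  expect_equal(assign_bin(0, gc_axis, 30), 0L)
  cov_axis <- axis_spec("cov", "log10", c(0.01, 100), clamp_min = 0.01)
  expect_equal(assign_bin(0.005, cov_axis, 30), 0L)  # clamped to the floor
  expect_equal(assign_bin(100, cov_axis, 30), 29L)
  expect_error(axis_spec("x", "linear", c(1, 1)), "lo < hi")
})

test_that("blob grids partition span and order concentric squares", {
  ds <- tiny_dataset(lengths = c(100, 300, 800, 50),
                     gc = c(0.31, 0.32, 0.71, 0.33),
                     cov = c(10, 10, 10, 10),
                     phylum = c("A", "B", "B", "A"))
  grid <- bin_blob(ds, x_field = "gc", y_field = "cov", cat_field = "phylum",
                   resolution = 10)
  expect_equal(sum(grid$cells$span), sum(field_values(ds, "length")))
  # c1, c2, c4 share a gc bin; categories drawn largest-first
  cell <- grid$cells[grid$cells$ix == 3, ]
  expect_equal(cell$category, c("B", "A"))
  expect_equal(cell$span, c(300, 150))
  expect_equal(cell$count, c(1L, 2L))
})

test_that("square sides follow the chosen scaling against the busiest cell", {
  ds <- tiny_dataset(lengths = c(100, 400), gc = c(0.11, 0.91),
                     cov = c(1, 1), phylum = c("A", "B"))
  grid <- bin_blob(ds, x_field = "gc", y_field = "cov", cat_field = "phylum",
                   resolution = 10, scale = "sqrt")
  sides <- setNames(grid$cells$side, grid$cells$category)
  expect_equal(sides[["B"]], 1.0)
  expect_equal(sides[["A"]], 0.5)  # sqrt(100)/sqrt(400)
  linear <- bin_blob(ds, x_field = "gc", y_field = "cov",
                     cat_field = "phylum", resolution = 10, scale = "linear")
  expect_equal(setNames(linear$cells$side, linear$cells$category)[["A"]], 0.25)
})

test_that("side scaling is monotone in span under every scale", {
  set.seed(3)
  lengths <- sample(100:10000, 40)
  ds <- tiny_dataset(lengths = lengths, gc = runif(40),
                     cov = runif(40, 0.1, 50), phylum = rep("A", 40))
  for (scale in c("sqrt", "linear", "log")) {
    grid <- bin_blob(ds, "gc", "cov", "phylum", resolution = 5, scale = scale)
    o <- order(grid$cells$span)
    expect_true(all(diff(grid$cells$side[o]) >= 0), label = scale)
    expect_equal(max(grid$cells$side), 1)
  }
})

test_that("bin selection inverts bin assignment and covers the dataset", {
  set.seed(4)
  n <- 30
  ds <- tiny_dataset(lengths = sample(100:1000, n), gc = runif(n),
                     cov = runif(n, 0.1, 80), phylum = rep("A", n))
  grid <- bin_blob(ds, "gc", "cov", "phylum", resolution = 6)
  seen <- character(0)
  for (r in seq_len(nrow(unique(grid$cells[, c("ix", "iy")])))) {
    cell <- unique(grid$cells[, c("ix", "iy")])[r, ]
    ids <- select_bin(grid, cell$ix, cell$iy, ds)
    expect_true(all(ids %in% ds$identifiers))
    seen <- c(seen, ids)
  }
  expect_setequal(seen, ds$identifiers)        # every contig in exactly one bin
  expect_equal(length(seen), length(ds$identifiers))
  expect_equal(select_bin(grid, 0, 5, ds),
               ds$identifiers[grid$contig_cells$ix == 0 &
                              grid$contig_cells$iy == 5])
  expect_error(select_bin(grid, 99, 0, ds), "outside grid")
})

test_that("hex binning also partitions the span", {
  set.seed(5)
  n <- 50
  ds <- tiny_dataset(lengths = sample(100:1000, n), gc = runif(n),
                     cov = runif(n, 0.1, 80), phylum = rep("A", n))
  grid <- bin_blob(ds, "gc", "cov", "phylum", resolution = 8, shape = "hex")
  expect_equal(sum(grid$cells$span), sum(field_values(ds, "length")))
  key <- paste(grid$contig_cells$ix, grid$contig_cells$iy)
  expect_equal(length(key), n)  # one cell per contig
})

test_that("kite statistics match the worked examples", {
  # equal-length contigs at x 0.4 and 0.6
  ds <- tiny_dataset(lengths = c(100, 100), gc = c(0.4, 0.6), cov = c(1, 1),
                     phylum = c("A", "A"))
  ks <- kite_stats(ds, "gc", "cov", "phylum",
                   x_axis = axis_spec("gc", "linear", c(0, 1)),
                   y_axis = axis_spec("cov", "linear", c(0, 2)))
  s <- ks$categories$A
  expect_equal(s$mean[["x"]], 0.5)
  expect_equal(s$sd[["x"]], 0.1)
  expect_equal(s$median[["x"]], 0.4)  # smallest value with cum weight >= half
  expect_equal(s$extent_x, c(0.3, 0.7))

  # weights 1 and 3 at x 0 and 1
  ds2 <- tiny_dataset(lengths = c(1, 3), gc = c(0, 1), cov = c(1, 1),
                      phylum = c("A", "A"))
  ks2 <- kite_stats(ds2, "gc", "cov", "phylum",
                    x_axis = axis_spec("gc", "linear", c(0, 1)),
                    y_axis = axis_spec("cov", "linear", c(0, 2)))
  expect_equal(ks2$categories$A$mean[["x"]], 0.75)

  # single contig: sd 0, slope 0, median at the point
  ds3 <- tiny_dataset(lengths = 100, gc = 0.4, cov = 2, phylum = "A")
  ks3 <- kite_stats(ds3, "gc", "cov", "phylum",
                    x_axis = axis_spec("gc", "linear", c(0, 1)),
                    y_axis = axis_spec("cov", "linear", c(0, 4)))
  expect_equal(ks3$categories$A$sd, c(x = 0, y = 0))
  expect_equal(ks3$categories$A$slope, 0)
  expect_equal(ks3$categories$A$median, c(x = 0.4, y = 2))
})

test_that("weighted moments match brute-force oracles", {
  set.seed(9)
  for (i in 1:100) {
    n <- sample(2:40, 1)
    x <- runif(n)
    y <- runif(n, 0, 5)
    w <- sample(100:5000, n, replace = TRUE)
    ds <- tiny_dataset(lengths = w, gc = x, cov = y, phylum = rep("A", n))
    ks <- kite_stats(ds, "gc", "cov", "phylum",
                     x_axis = axis_spec("gc", "linear", c(0, 1)),
                     y_axis = axis_spec("cov", "linear", c(0, 5)))
    s <- ks$categories$A
    expect_equal(s$mean[["x"]], oracle_wmean(x, w), tolerance = 1e-9)
    expect_equal(s$sd[["x"]], oracle_wsd(x, w), tolerance = 1e-9)
    expect_equal(s$median[["x"]], oracle_wmedian(x, w))
    expect_equal(s$slope, oracle_wslope(x, y, w), tolerance = 1e-9)
    expect_equal(s$intercept,
                 oracle_wmean(y, w) - s$slope * oracle_wmean(x, w),
                 tolerance = 1e-9)
  }
})

test_that("equal weights reduce weighted statistics to unweighted ones", {
  set.seed(10)
  x <- runif(20)
  ds <- tiny_dataset(lengths = rep(100, 20), gc = x, cov = runif(20, 0, 5),
                     phylum = rep("A", 20))
  ks <- kite_stats(ds, "gc", "cov", "phylum",
                   x_axis = axis_spec("gc", "linear", c(0, 1)),
                   y_axis = axis_spec("cov", "linear", c(0, 5)))
  expect_equal(ks$categories$A$mean[["x"]], mean(x))
  expect_equal(ks$categories$A$sd[["x"]],
               sqrt(mean((x - mean(x))^2)))
})

test_that("cumulative curves sort, accumulate and stack by span", {
  ds <- tiny_dataset(lengths = c(5, 3, 4), gc = c(0.3, 0.3, 0.5),
                     cov = c(1, 1, 1), phylum = c("A", "A", "B"))
  cc <- cumulative_curves(ds, "phylum")
  expect_equal(cc$overall$span, c(5, 9, 12))
  expect_equal(cc$curves$A$span, c(5, 8))
  expect_equal(cc$curves$B$span, 4)
  expect_equal(names(cc$curves), c("A", "B"))  # by descending span
  expect_equal(sum(vapply(cc$curves, function(cv) max(cv$span), numeric(1))),
               cc$total_span)
  # concavity: increments never increase
  expect_true(all(diff(diff(c(0, cc$overall$span))) <= 0))
})

test_that("nx statistics follow the first-reach definition", {
  expect_equal(nx_statistic(c(8, 5, 4, 3), 0.5), 5)
  expect_equal(nx_statistic(7, 0.1), 7)
  expect_equal(nx_statistic(c(4, 4, 4, 4), 0.9), 4)
  expect_error(nx_statistic(numeric(0), 0.5), "empty")
  expect_error(nx_statistic(5, 1), "fraction")
  set.seed(12)
  for (i in 1:100) {
    l <- sample(1:5000, sample(1:60, 1), replace = TRUE)
    expect_equal(nx_statistic(l, 0.5), oracle_nx(l, 0.5))
    expect_gte(nx_statistic(l, 0.5), nx_statistic(l, 0.9))
  }
})

test_that("snail statistics summarise the assembly", {
  ds <- tiny_dataset(lengths = c(8, 5, 4, 3), gc = c(0.4, 0.6, 0.5, 0.5),
                     cov = c(1, 1, 1, 1), phylum = rep("A", 4))
  sn <- snail_stats(ds, segments = 20)
  expect_equal(sn$span, 20)
  expect_equal(sn$longest, 8)
  expect_equal(sn$n50, 5)
  expect_equal(sn$n90, 3)   # cum 8,13,17,20; 18 first reached at the 4th
  expect_equal(sn$gc, sum(c(0.4, 0.6, 0.5, 0.5) * c(8, 5, 4, 3)) / 20)
  expect_equal(sn$at, 1 - sn$gc)
  expect_true(all(diff(sn$segment_length) <= 0))
  expect_equal(sn$segment_length[1], 8)
  expect_equal(sn$segment_length[20], 3)

  single <- tiny_dataset(lengths = 500, gc = 0.5, cov = 1, phylum = "A")
  sn1 <- snail_stats(single, segments = 10)
  expect_true(all(sn1$segment_length == 500))
  expect_true(all(sn1$segment_gc[, "mean"] == 0.5))

  # gc of equal-length contigs averages plainly
  eq <- tiny_dataset(lengths = c(100, 100), gc = c(0.4, 0.6), cov = c(1, 1),
                     phylum = c("A", "A"))
  expect_equal(snail_stats(eq, segments = 4)$gc, 0.5)
})

test_that("busco summaries recompute statuses under a mask", {
  ds <- tiny_dataset()
  table_path <- write_busco_table(c("b1\tComplete\tc1\t1\t10",
                                    "b2\tComplete\tc1\t1\t10",
                                    "b2\tComplete\tc2\t1\t10",
                                    "b3\tFragmented\tc3\t1\t10",
                                    "b4\tMissing"))
  # rows listing one id complete on two contigs arrive as Duplicated pairs
  busco <- parse_busco_table(table_path, "toy_odb1")
  ds <- add_busco_field(ds, busco)

  all_in <- busco_summary(ds, lineage = "toy_odb1")
  expect_equal(all_in[["Complete"]], 1L)
  expect_equal(all_in[["Duplicated"]], 1L)
  expect_equal(all_in[["Fragmented"]], 1L)
  expect_equal(all_in[["Missing"]], 1L)

  # filtering out c2 demotes b2 to single-copy Complete
  drop_c2 <- busco_summary(ds, c(TRUE, FALSE, TRUE, TRUE), "toy_odb1")
  expect_equal(drop_c2[["Complete"]], 2L)
  expect_equal(drop_c2[["Duplicated"]], 0L)

  # filtering out c1 loses b1 entirely
  drop_c1 <- busco_summary(ds, c(FALSE, TRUE, TRUE, TRUE), "toy_odb1")
  expect_equal(drop_c1[["Missing"]], 2L)
  expect_equal(sum(drop_c1), busco$total)

  expect_error(busco_summary(ds, lineage = "nope"), "unknown BUSCO lineage")
})

test_that("busco summary counts always sum to the lineage total", {
  set.seed(13)
  ds <- tiny_dataset()
  rows <- c("b1\tComplete\tc1\t1\t2", "b2\tDuplicated\tc1\t1\t2",
            "b2\tDuplicated\tc3\t1\t2", "b3\tFragmented\tc4\t1\t2",
            "b4\tMissing", "b5\tComplete\tc2\t1\t2")
  ds <- add_busco_field(ds, parse_busco_table(write_busco_table(rows),
                                              "toy_odb1"))
  for (i in 1:50) {
    mask <- runif(4) < 0.5
    counts <- busco_summary(ds, mask, "toy_odb1")
    expect_equal(sum(counts), 5L)
  }
})

test_that("busco category selection returns carrying contigs in order", {
  ds <- tiny_dataset()
  rows <- c("b1\tComplete\tc1\t1\t2", "b2\tFragmented\tc1\t1\t2",
            "b3\tComplete\tc3\t1\t2", "b4\tMissing")
  ds <- add_busco_field(ds, parse_busco_table(write_busco_table(rows),
                                              "toy_odb1"))
  expect_equal(busco_category_ids(ds, "toy_odb1", "Complete"), c("c1", "c3"))
  expect_equal(busco_category_ids(ds, "toy_odb1", "Fragmented"), "c1")
  expect_equal(busco_category_ids(ds, "toy_odb1", "Missing"), character(0))
  expect_error(busco_category_ids(ds, "toy_odb1", "Nope"), "unknown BUSCO status")
})

test_that("contig hit layouts resolve names and respect contig bounds", {
  td <- fixture_taxdump()
  ds <- tiny_dataset()
  hits <- data.frame(query_id = c("c1", "c1"), taxid = c(435L, 1580L),
                     bitscore = c(100, 60), subject_id = "s",
                     qstart = c(10L, 200L), qend = c(60L, 260L),
                     db_index = 0L)
  tax <- apply_taxrule(hits, td, ds$identifiers, "bestsum")
  ds <- add_taxonomy_fields(ds, tax)
  layout <- contig_hit_layout(ds, "c1", rank = "phylum")
  expect_equal(nrow(layout), 2L)
  expect_equal(layout$taxon, c("Proteobacteria", "Firmicutes"))
  expect_equal(layout$qstart, c(10, 200))
  expect_true(all(layout$qend <= field_values(ds, "length")[1]))
  expect_equal(nrow(contig_hit_layout(ds, "c2")), 0L)
  expect_error(contig_hit_layout(ds, "zz"), "unknown contig")
})

test_that("view defaults follow the large-dataset thresholds", {
  expect_equal(view_defaults(5000)$mode, "circle")
  expect_equal(view_defaults(100000)$mode, "binned")
  expect_false(view_defaults(999999)$filter_nohit)
  expect_true(view_defaults(1000001)$filter_nohit)
})

test_that("filtered-view coherence: binning after filtering drops masked cells", {
  set.seed(14)
  n <- 40
  ds <- tiny_dataset(lengths = sample(100:2000, n), gc = runif(n),
                     cov = runif(n, 0.1, 60),
                     phylum = sample(c("A", "B"), n, replace = TRUE))
  xa <- axis_spec("gc", "linear", c(0, 1))
  ya <- axis_spec("cov", "log10", c(0.01, 100), clamp_min = 0.01)
  mask <- build_mask(ds, filter_params(variable = list(gc = list(max = 0.5))))
  direct <- bin_blob(filter_dataset(ds, mask), "gc", "cov", "phylum",
                     resolution = 8, x_axis = xa, y_axis = ya)
  full <- bin_blob(ds, "gc", "cov", "phylum", resolution = 8,
                   x_axis = xa, y_axis = ya)
  # recompute full-grid cell spans restricted to retained contigs
  keep_key <- paste(full$contig_cells$ix, full$contig_cells$iy,
                    field_values(ds, "phylum"))[mask]
  expect_equal(
    sort(tapply(field_values(ds, "length")[mask], keep_key, sum)),
    sort(setNames(direct$cells$span,
                  paste(direct$cells$ix, direct$cells$iy,
                        direct$cells$category))),
    ignore_attr = TRUE)
  expect_equal(sum(direct$cells$span), sum(field_values(ds, "length")[mask]))
})

test_that("svg rendering is deterministic and structurally sound", {
  ds <- tiny_dataset()
  grid <- bin_blob(ds, "gc", "cov", "phylum", resolution = 10)
  svg1 <- render_svg(grid)
  svg2 <- render_svg(grid)
  expect_identical(svg1, svg2)
  expect_match(svg1, "^<svg xmlns")
  n_cells <- nrow(grid$cells)
  expect_equal(lengths(regmatches(svg1, gregexpr('id="cell-', svg1))), n_cells)

  for (maker in list(function() kite_stats(ds, "gc", "cov", "phylum"),
                     function() cumulative_curves(ds, "phylum"),
                     function() snail_stats(ds, segments = 50))) {
    out <- render_svg(maker())
    expect_match(out, "</svg>")
  }
  path <- tempfile(fileext = ".svg")
  render_svg(grid, path = path)
  expect_identical(paste(readLines(path), collapse = "\n"),
                   sub("\n$", "", svg1))
})
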