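test_that("overlap proportion handles full, half and zero overlap exactly", {
  g <- toy_grid(4, 4, dlon = 0.5)
  inside <- matrix(FALSE, 4, 4); inside[1:2, ] <- TRUE   # western half of grid
  layer <- layer_from_matrix(g, inside)
  # 1x1 square straddling the layer edge at the same latitudes: exactly half
  r <- rect_range("straddle", 0.5, 1.5, 0.5, 1.5)
  ov <- overlap_proportion(r, layer)
  expect_equal(ov$proportion, 0.5, tolerance = 1e-12)
  # fully inside
  rin <- rect_range("in", 0.1, 0.9, 0.1, 0.9)
  expect_equal(overlap_proportion(rin, layer)$proportion, 1.0)
  # fully outside
  rout <- rect_range("out", 1.6, 1.9, 0.1, 0.9)
  expect_equal(overlap_proportion(rout, layer)$proportion, 0.0)
  # zero-area range on the grid errors
  rfar <- rect_range("far", 30, 31, 30, 31)
  expect_error(overlap_proportion(rfar, layer), "zero area")
})

test_that("overlap areas match the closed-form rectangle oracle", {
  set.seed(21)
  g <- toy_grid(8, 8, dlon = 0.5)
  inside <- matrix(runif(64) < 0.5, 8, 8)
  layer <- layer_from_matrix(g, inside)
  for (k in 1:20) {
    xr <- sort(runif(2, 0, 4)); yr <- sort(runif(2, 0, 4))
    if (diff(xr) < 0.1 || diff(yr) < 0.1) next
    r <- rect_range(paste0("r", k), xr[1], xr[2], yr[1], yr[2])
    oracle <- rect_cell_area_oracle(xr[1], xr[2], yr[1], yr[2], g)
    ov <- overlap_proportion(r, layer)
    expect_equal(ov$total_km2, sum(oracle), tolerance = 1e-9)
    expect_equal(ov$overlap_km2, sum(oracle[inside]), tolerance = 1e-9)
  }
})

test_that("random multipart ranges agree with the fine-rasterization oracle", {
  set.seed(31)
  g <- toy_grid(8, 8, dlon = 0.5)
  inside <- matrix(runif(64) < 0.4, 8, 8)
  layer <- layer_from_matrix(g, inside)
  for (k in 1:30) {
    r <- random_range(paste0("r", k), g, max_span = 2)
    want <- overlap_oracle(r, layer, step = 0.02)
    got <- overlap_proportion(r, layer)$proportion
    expect_lt(abs(got - want), 1e-3)
  }
})

test_that("splitting a polygon into adjacent halves leaves the proportion unchanged", {
  g <- toy_grid(6, 6, dlon = 0.5)
  inside <- matrix(FALSE, 6, 6); inside[, 4:6] <- TRUE
  layer <- layer_from_matrix(g, inside)
  whole <- rect_range("w", 0.3, 2.3, 0.4, 2.7)
  halves <- species_range("h", list(
    cbind(c(0.3, 1.3, 1.3, 0.3), c(0.4, 0.4, 2.7, 2.7)),
    cbind(c(1.3, 2.3, 2.3, 1.3), c(0.4, 0.4, 2.7, 2.7))))
  expect_equal(overlap_proportion(halves, layer)$proportion,
               overlap_proportion(whole, layer)$proportion, tolerance = 1e-9)
})

test_that("overlapping multipart unions are not double counted", {
  g <- toy_grid(4, 4, dlon = 1)
  inside <- matrix(TRUE, 4, 4)
  layer <- layer_from_matrix(g, inside)
  # two rectangles overlapping inside one cell; union area < sum of parts
  r <- species_range("u", list(
    cbind(c(0.2, 0.8, 0.8, 0.2), c(0.2, 0.2, 0.8, 0.8)),
    cbind(c(0.5, 1.1, 1.1, 0.5), c(0.2, 0.2, 0.8, 0.8))))
  got <- overlap_proportion(r, layer)$total_km2
  oracle <- rect_cell_area_oracle(0.2, 1.1, 0.2, 0.8, g)  # the true union
  expect_equal(got, sum(oracle), tolerance = 5e-3 * sum(oracle))
})

test_that("classification is strict at the cutoff", {
  expect_true(classify_exposed(0.51))
  expect_false(classify_exposed(0.50))
  expect_false(classify_exposed(0.0))
  expect_true(classify_exposed(0.31, cutoff = 0.3))
})

test_that("adding layer cells never decreases the proportion", {
  set.seed(41)
  g <- toy_grid(6, 6, dlon = 0.5)
  r <- random_range("mono", g, max_span = 2)
  inside <- matrix(FALSE, 6, 6)
  prev <- 0
  for (k in sample(36)) {
    inside[k] <- TRUE
    p <- overlap_proportion(r, layer_from_matrix(g, inside))$proportion
    expect_gte(p, prev - 1e-12)
    prev <- p
  }
  expect_equal(prev, 1.0)
})

test_that("excess events summarize the difference field over the range", {
  g <- toy_grid(4, 4, dlon = 1)
  d <- diff_from_matrix(g, matrix(14, 4, 4))
  r <- rect_range("c", 0.5, 2.5, 0.5, 2.5)
  ex <- excess_events_in_range(r, d)
  expect_equal(ex$mean, 14)                     # constant field, mean 14
  expect_equal(ex$weighted_mean, 14)
  # single-cell range: mean is that cell's value
  vals <- matrix(as.numeric(1:16), 4, 4)
  d2 <- diff_from_matrix(g, vals)
  r1 <- rect_range("one", 1.2, 1.8, 2.2, 2.8)   # inside cell (2, 3)
  expect_equal(excess_events_in_range(r1, d2)$mean, vals[2, 3])
  # random rectangle equals brute-force enumeration over intersected cells
  set.seed(51)
  for (k in 1:10) {
    xr <- sort(runif(2, 0, 4)); yr <- sort(runif(2, 0, 4))
    if (diff(xr) < 0.2 || diff(yr) < 0.2) next
    rr <- rect_range("e", xr[1], xr[2], yr[1], yr[2])
    areas <- rect_cell_area_oracle(xr[1], xr[2], yr[1], yr[2], g)
    hit <- areas > 0
    ex2 <- excess_events_in_range(rr, d2)
    expect_equal(ex2$mean, mean(vals[hit]))
    expect_equal(ex2$sum, sum(vals[hit]))
    expect_equal(ex2$weighted_mean, sum(vals[hit] * areas[hit]) / sum(areas[hit]),
                 tolerance = 1e-9)
  }
  # no unmasked intersected cells: flagged record with NA summaries
  dna <- diff_from_matrix(g, matrix(NA_real_, 4, 4))
  exna <- excess_events_in_range(r, dna)
  expect_true(exna$no_cells)
  expect_true(is.na(exna$mean))
})

test_that("exposure_table produces one consistent record per species and class", {
  g <- toy_grid(4, 4, dlon = 1)
  inside <- matrix(FALSE, 4, 4); inside[1:2, ] <- TRUE
  layers <- list(heat_wave = layer_from_matrix(g, inside),
                 drought = layer_from_matrix(g, matrix(TRUE, 4, 4), "drought"))
  diffs <- list(heat_wave = diff_from_matrix(g, matrix(3, 4, 4)),
                drought = diff_from_matrix(g, matrix(5, 4, 4), "drought"))
  ranges <- list(rect_range("a", 0.2, 1.8, 0.2, 1.8),
                 rect_range("b", 2.2, 3.8, 0.2, 1.8))
  tab <- exposure_table(ranges, layers, diffs)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$proportion[tab$species_id == "a" & tab$event_class == "heat_wave"], 1)
  expect_equal(tab$proportion[tab$species_id == "b" & tab$event_class == "heat_wave"], 0)
  expect_true(all(tab$exposed[tab$event_class == "drought"]))
  expect_true(all(tab$overlap_km2 <= tab$total_km2 + 1e-9))
  expect_equal(tab$excess_mean[tab$event_class == "drought"], c(5, 5))
})
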