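# Shared fixtures and independent oracles (all generated in code).

# Small grid helpers -------------------------------------------------------

toy_grid <- function(nlon = 4, nlat = 4, dlon = 0.5, lon0 = 0, lat0 = 0) {
  grid_from_extent(c(lon0, lon0 + nlon * dlon), c(lat0, lat0 + nlat * dlon), dlon)
}

# A temperature cube whose values are supplied per cell as a function of
# (i, j) returning the daily series.
cube_from_series <- function(grid, dates, series_fun) {
  nd <- dim_grid(grid)
  values <- array(NA_real_, c(nd[1], nd[2], length(dates)))
  for (j in seq_len(nd[2])) for (i in seq_len(nd[1]))
    values[i, j, ] <- series_fun(i, j)
  temperature_cube(grid, dates, values)
}

days_of <- function(year_from, year_to) {
  seq(as.Date(sprintf("%d-01-01", year_from)),
      as.Date(sprintf("%d-12-31", year_to)), by = "day")
}

months_of <- function(year_from, year_to) {
  seq(as.Date(sprintf("%d-01-01", year_from)),
      as.Date(sprintf("%d-12-01", year_to)), by = "month")
}

# Rectangle range helper ----------------------------------------------------

rect_range <- function(id, xmin, xmax, ymin, ymax, ...) {
  species_range(id, cbind(c(xmin, xmax, xmax, xmin),
                          c(ymin, ymin, ymax, ymax)), ...)
}

# Axis-aligned rectangle / grid-cell intersection area on the sphere:
# independent closed form (interval overlap in lon, sin-lat band overlap).
rect_cell_area_oracle <- function(xmin, xmax, ymin, ymax, grid, R = 6371) {
  nd <- dim_grid(grid)
  out <- matrix(0, nd[1], nd[2])
  for (j in seq_len(nd[2])) for (i in seq_len(nd[1])) {
    b <- c(grid$lon[i] - grid$dlon / 2, grid$lon[i] + grid$dlon / 2,
           grid$lat[j] - grid$dlat / 2, grid$lat[j] + grid$dlat / 2)
    dx <- max(0, min(xmax, b[2]) - max(xmin, b[1]))
    y1 <- max(ymin, b[3]); y2 <- min(ymax, b[4])
    if (dx > 0 && y2 > y1)
      out[i, j] <- R^2 * dx * pi / 180 * (sin(y2 * pi / 180) - sin(y1 * pi / 180))
  }
  out
}

# Exhaustive day-by-day scan oracle for run detection ----------------------

scan_runs_oracle <- function(series, threshold, direction, min_len) {
  exceed <- if (direction == "above") series > threshold else series < threshold
  exceed[is.na(exceed)] <- FALSE
  events <- data.frame(start = integer(0), length = integer(0))
  run <- 0L
  for (t in seq_along(exceed)) {
    if (exceed[t]) run <- run + 1L
    if ((!exceed[t] || t == length(exceed)) && run > 0L) {
      end <- if (exceed[t]) t else t - 1L
      if (run >= min_len)
        events <- rbind(events, data.frame(start = end - run + 1L, length = run))
      run <- 0L
    }
  }
  events
}

# Fine-rasterization overlap oracle (0.02 degree subcells, area-weighted;
# per-subcell coverage estimated by a 3x3 quadrature) -----------------------

# One polygon part rasterized to 0.02 degree subcells: returns
# c(total_area, overlap_area) with per-subcell coverage from a 3x3
# quadrature (no systematic bias on slanted edges).
part_oracle_fine <- function(part, layer, step = 0.02, R = 6371) {
  g <- layer$grid
  bb <- c(min(part[, 1]), max(part[, 1]), min(part[, 2]), max(part[, 2]))
  xr <- c(max(bb[1], min(g$lon) - g$dlon / 2), min(bb[2], max(g$lon) + g$dlon / 2))
  yr <- c(max(bb[3], min(g$lat) - g$dlat / 2), min(bb[4], max(g$lat) + g$dlat / 2))
  if (diff(xr) <= 0 || diff(yr) <= 0) return(c(0, 0))
  # snap the subcell lattice to the grid's cell edges so every subcell
  # nests inside exactly one layer cell (step divides the cell size)
  ox <- min(g$lon) - g$dlon / 2; oy <- min(g$lat) - g$dlat / 2
  xs <- ox + (floor((xr[1] - ox) / step):(ceiling((xr[2] - ox) / step) - 1) + 0.5) * step
  ys <- oy + (floor((yr[1] - oy) / step):(ceiling((yr[2] - oy) / step) - 1) + 0.5) * step
  px0 <- rep(xs, times = length(ys))
  py0 <- rep(ys, each = length(xs))
  w <- R^2 * (step * pi / 180) *
    (sin((py0 + step / 2) * pi / 180) - sin((py0 - step / 2) * pi / 180))
  cover <- numeric(length(px0))
  off <- (step / 5) * (-2:2)
  for (dx in off) for (dy in off)
    cover <- cover + amphex:::point_in_ring(px0 + dx, py0 + dy, part)
  cover <- cover / 25
  ci <- findInterval(px0, c(g$lon - g$dlon / 2, max(g$lon) + g$dlon / 2),
                     rightmost.closed = TRUE)
  cj <- findInterval(py0, c(g$lat - g$dlat / 2, max(g$lat) + g$dlat / 2),
                     rightmost.closed = TRUE)
  ok <- cover > 0 & ci >= 1 & ci <= length(g$lon) & cj >= 1 & cj <= length(g$lat)
  if (!any(ok)) return(c(0, 0))
  hit <- layer$inside[cbind(ci[ok], cj[ok])]
  wc <- w[ok] * cover[ok]
  c(sum(wc), sum(wc[hit]))
}

is_axis_rect <- function(p) {
  nrow(p) == 4L && length(unique(p[, 1])) == 2L && length(unique(p[, 2])) == 2L
}

# Independent overlap oracle, composed part by part (parts are
# bbox-disjoint): axis-aligned rectangles use the exact closed-form
# interval overlap, anything else the fine rasterization.
overlap_oracle <- function(range, layer, step = 0.02, R = 6371) {
  tot <- 0; ov <- 0
  for (p in range$parts) {
    if (is_axis_rect(p)) {
      areas <- rect_cell_area_oracle(min(p[, 1]), max(p[, 1]),
                                     min(p[, 2]), max(p[, 2]), layer$grid, R)
      tot <- tot + sum(areas)
      ov <- ov + sum(areas[layer$inside])
    } else {
      to <- part_oracle_fine(p, layer, step, R)
      tot <- tot + to[1]
      ov <- ov + to[2]
    }
  }
  if (tot <= 0) return(NA_real_)
  ov / tot
}

# Random synthetic ranges for oracle comparisons ---------------------------

random_range <- function(id, grid, max_span = 3) {
  lonr <- range(grid$lon) + c(-1, 1) * grid$dlon / 2
  latr <- range(grid$lat) + c(-1, 1) * grid$dlat / 2
  nparts <- sample(1:2, 1)
  parts <- list()
  tries <- 0L
  while (length(parts) < nparts && tries < 50L) {
    tries <- tries + 1L
    w <- runif(1, 0.2, max_span); h <- runif(1, 0.2, max_span)
    x0 <- runif(1, lonr[1], lonr[2] - w)
    y0 <- runif(1, latr[1], latr[2] - h)
    part <- if (runif(1) < 0.5) {
      cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
    } else {
      pts <- cbind(runif(10, x0, x0 + w), runif(10, y0, y0 + h))
      pts[grDevices::chull(pts), , drop = FALSE]
    }
    bb <- c(x0, x0 + w, y0, y0 + h)
    clash <- any(vapply(parts, function(p)
      min(p[, 1]) < bb[2] && bb[1] < max(p[, 1]) &&
      min(p[, 2]) < bb[4] && bb[3] < max(p[, 2]), logical(1)))
    if (!clash) parts[[length(parts) + 1L]] <- part
  }
  species_range(id, parts)
}

# Hazard layer with a given inside matrix ----------------------------------

layer_from_matrix <- function(grid, inside, event_class = "heat_wave") {
  structure(list(grid = grid, inside = inside, event_class = event_class,
                 threshold_value = 1, threshold_rule = ge_threshold(1)),
            class = "hazard_layer")
}

diff_from_matrix <- function(grid, values, event_class = "heat_wave") {
  structure(list(grid = grid, values = values, event_class = event_class),
            class = "difference_field")
}

# Exposure-record builder for tally arithmetic -----------------------------

make_exposure <- function(n, exposed_by_class) {
  ids <- sprintf("sp%05d", seq_len(n))
  do.call(rbind, lapply(names(exposed_by_class), function(cls) {
    data.frame(species_id = ids, event_class = cls,
               proportion = as.numeric(seq_len(n) <= exposed_by_class[[cls]]),
               exposed = seq_len(n) <= exposed_by_class[[cls]])
  }))
}
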