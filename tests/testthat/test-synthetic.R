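small_scenario <- function(seed = 1, n_species = 40L, ...) {
  synthetic_scenario(seed = seed, lon_range = c(-66, -62), lat_range = c(-6, -2),
                     dlon = 1, n_species = n_species, ...)
}

test_that("generators are deterministic under a fixed seed", {
  sc <- small_scenario(seed = 9)
  expect_identical(gen_temperature_cube(sc, "baseline")$values,
                   gen_temperature_cube(sc, "baseline")$values)
  expect_identical(gen_spei_cube(sc)$values, gen_spei_cube(sc)$values)
  g1 <- gen_ranges(sc); g2 <- gen_ranges(sc)
  expect_identical(g1$ranges[[5]]$parts, g2$ranges[[5]]$parts)
  expect_identical(g1$taxonomy, g2$taxonomy)
  ex <- data.frame(species_id = as.character(1:100), heat_exposure = runif(100),
                   drought_exposure = 0, cold_exposure = 0)
  expect_identical(gen_status_changes(ex, seed = 3)$outcome,
                   gen_status_changes(ex, seed = 3)$outcome)
})

test_that("zero trend and zero noise give identical decades and a zero difference field", {
  sc <- small_scenario(warming_trend = 0, ar_sd = 0)
  cb <- gen_temperature_cube(sc, "baseline")
  cr <- gen_temperature_cube(sc, "recent")
  thr <- compute_percentile_threshold(cb, 90, range(cb$dates))
  mb <- monthly_event_counts(cb, thr, "above", 6)
  mr <- monthly_event_counts(cr, thr, "above", 6)
  d <- difference_field(decadal_count(mr, sc$recent_decade),
                        decadal_count(mb, sc$baseline_decade))
  expect_true(all(d$values == 0L))
})

test_that("a strong warming trend raises recent heat-event counts in most cells", {
  positive <- integer(0)
  for (seed in 1:20) {
    sc <- synthetic_scenario(seed = seed, lon_range = c(-64, -62),
                             lat_range = c(-4, -2), dlon = 1,
                             warming_trend = 1.5)
    cb <- gen_temperature_cube(sc, "baseline")
    cr <- gen_temperature_cube(sc, "recent")
    thr <- compute_percentile_threshold(cb, 90, range(cb$dates))
    d <- difference_field(
      decadal_count(monthly_event_counts(cr, thr, "above", 6), sc$recent_decade),
      decadal_count(monthly_event_counts(cb, thr, "above", 6), sc$baseline_decade))
    positive <- c(positive, sum(d$values > 0))
  }
  expect_gte(mean(positive) / 4, 0.8)   # >= 80% of the 4 cells, on average
})

test_that("SPEI drought frequency follows the normal closed form", {
  sc <- synthetic_scenario(seed = 12, lon_range = c(-70, -60),
                           lat_range = c(-10, 0), dlon = 1,
                           spei_trend_per_decade = 0)
  sp <- gen_spei_cube(sc, "both")
  freq <- mean(sp$values < -1.5)
  expect_lt(abs(freq - pnorm(-1.5)), 0.01)             # ~0.0668
  # recent-decade shift of -0.5 moves the frequency to ~ Phi(-1.0)
  sc2 <- synthetic_scenario(seed = 12, lon_range = c(-70, -60),
                            lat_range = c(-10, 0), dlon = 1,
                            spei_trend_per_decade = -0.5 / 3)
  sp2 <- gen_spei_cube(sc2, "both")
  yr <- as.integer(format(sp2$months, "%Y"))
  recent <- yr >= 2010
  expect_lt(abs(mean(sp2$values[, , recent] < -1.5) - pnorm(-1.0)), 0.015)
  expect_lt(abs(mean(sp2$values[, , !recent] < -1.5) - pnorm(-1.5)), 0.01)
})

test_that("generated ranges respect the extent and the size distribution", {
  sc <- synthetic_scenario(seed = 13, n_species = 1000L)
  gen <- gen_ranges(sc)
  planar_area <- function(r) sum(vapply(r$parts, amphex:::planar_ring_area,
                                        numeric(1)))
  areas <- vapply(gen$ranges, planar_area, numeric(1))
  for (r in gen$ranges) for (p in r$parts) {
    expect_true(all(p[, 1] >= sc$lon_range[1] - 1e-9 &
                    p[, 1] <= sc$lon_range[2] + 1e-9))
    expect_true(all(p[, 2] >= sc$lat_range[1] - 1e-9 &
                    p[, 2] <= sc$lat_range[2] + 1e-9))
  }
  # log-uniform between 0.25 and 25 deg^2: median sqrt(0.25 * 25) = 2.5
  lo <- log(sc$area_range_deg2[1]); hi <- log(sc$area_range_deg2[2])
  expect_lt(abs(median(log(areas)) - (lo + hi) / 2), 0.15)
  expect_lt(abs(quantile(log(areas), 0.25, names = FALSE) -
                  (lo + 0.25 * (hi - lo))), 0.2)
  expect_lt(abs(quantile(log(areas), 0.75, names = FALSE) -
                  (lo + 0.75 * (hi - lo))), 0.2)
  expect_true(any(vapply(gen$ranges, function(r) length(r$parts) > 1L, logical(1))))
  # disjunct parts never overlap
  for (r in gen$ranges) if (length(r$parts) > 1L)
    for (a in 1:(length(r$parts) - 1)) for (b in (a + 1):length(r$parts))
      expect_false(amphex:::bbox_overlap(amphex:::ring_bbox(r$parts[[a]]),
                                         amphex:::ring_bbox(r$parts[[b]])))
})

test_that("status outcomes follow the multinomial-logit closed form", {
  n <- 20000
  ex <- data.frame(species_id = as.character(1:n), heat_exposure = runif(n),
                   drought_exposure = runif(n), cold_exposure = runif(n))
  null_params <- list(uplisted = c(intercept = 0.03, heat = 1, drought = 1, cold = 1),
                      downlisted = c(intercept = 0.02, heat = 1, drought = 1, cold = 1))
  st <- gen_status_changes(ex, null_params, seed = 14)
  f <- table(st$outcome) / n
  expect_lt(abs(f[["no_change"]] - 1 / 1.05), 0.005)      # ~0.952
  expect_lt(abs(f[["uplisted"]] - 0.03 / 1.05), 0.003)    # ~0.0286
  expect_lt(abs(f[["downlisted"]] - 0.02 / 1.05), 0.003)  # ~0.0190
  # an enormous heat odds ratio with full exposure forces uplisting
  big <- list(uplisted = c(intercept = 0.03, heat = 1e8, drought = 1, cold = 1),
              downlisted = c(intercept = 0.02, heat = 1, drought = 1, cold = 1))
  ex1 <- data.frame(species_id = as.character(1:500), heat_exposure = 1,
                    drought_exposure = 0, cold_exposure = 0)
  st1 <- gen_status_changes(ex1, big, seed = 15)
  expect_true(all(st1$outcome == "uplisted"))
})

test_that("planted hazard membership yields the exact exposure labels", {
  g <- toy_grid(6, 6, dlon = 1)
  inside <- matrix(FALSE, 6, 6); inside[1:3, ] <- TRUE
  layer <- layer_from_matrix(g, inside)
  r_in <- rect_range("planted_in", 0.5, 2.5, 1, 5)      # wholly inside
  r_out <- rect_range("planted_out", 3.5, 5.5, 1, 5)    # wholly outside
  expect_true(classify_exposed(overlap_proportion(r_in, layer)$proportion))
  expect_false(classify_exposed(overlap_proportion(r_out, layer)$proportion))
})

test_that("the full synthetic pipeline runs end to end coherently", {
  sc <- small_scenario(seed = 17)
  res <- suppressWarnings(run_synthetic_pipeline(sc))
  expect_equal(nrow(res$exposure), 3L * sc$n_species)
  expect_true(all(res$exposure$proportion >= 0 & res$exposure$proportion <= 1))
  expect_true(all(res$exposure$overlap_km2 <= res$exposure$total_km2 + 1e-6))
  expect_equal(sort(names(res$layers)), c("cold_spell", "drought", "heat_wave"))
  expect_equal(sum(res$multi$combinations$n_species), sc$n_species)
  expect_true(all(res$grid_summary$exposed_count$heat_wave <=
                    res$grid_summary$richness))
  # at 40 species a simulated outcome level can be absent; the fit is then
  # reported as NULL, otherwise it must have converged
  if (!is.null(res$fit)) expect_true(res$fit$converged)
})

test_that("the pipeline's status fit converges when every outcome is represented", {
  sc <- small_scenario(seed = 19, n_species = 250L)
  res <- suppressMessages(suppressWarnings(run_synthetic_pipeline(sc)))
  expect_false(is.null(res$fit))
  expect_true(res$fit$converged)
  expect_true(all(or_table(res$fit)$odds_ratio > 0))
})
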