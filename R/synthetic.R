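#' Synthetic study scenario
#'
#' Bundles every knob of the synthetic-data generators: grid geometry,
#' years, the temperature process (climatology + seasonal cycle + linear
#' warming trend + AR(1) noise), the SPEI process (standard-normal
#' marginals with a drying trend), the species-range generator and the
#' true status-model parameters. Identical seeds give identical outputs.
#'
#' Defaults describe a desk-scale tropical domain: a 20 x 20 grid of 0.5
#' degree cells, the 1980-1989 and 2010-2019 decades, 300 species, a 0.3
#' degC/decade warming trend and a -0.2 SPEI-unit/decade drying trend.
#'
#' @param seed Integer RNG seed.
#' @param lon_range,lat_range Domain extents in degrees (cell edges).
#' @param dlon Cell size in degrees (square cells).
#' @param baseline_decade,recent_decade Year ranges.
#' @param base_temp Mean annual temperature at the domain centre (degC).
#' @param lat_gradient degC per degree latitude away from the domain centre.
#' @param seasonal_amp Amplitude (degC) of the seasonal sinusoid.
#' @param warming_trend degC per decade, linear from the baseline start.
#' @param ar_phi,ar_sd AR(1) day-to-day autocorrelation and marginal
#'   standard deviation of the temperature noise (`|phi| < 1`).
#' @param spei_trend_per_decade SPEI units per decade of mean drying (the
#'   recent-decade mean shift is this times the decade gap between period
#'   midpoints).
#' @param spei_phi Month-to-month AR(1) autocorrelation of SPEI noise
#'   (marginals remain standard normal).
#' @param n_species Number of species ranges.
#' @param area_range_deg2 Range-size span; areas are log-uniform between
#'   these planar-degree^2 bounds.
#' @param disjunct_prob Probability a species gets 2-3 disjunct parts.
#' @param blob_prob Probability a part is a convex blob rather than a
#'   rectangle.
#' @param n_families Number of synthetic families.
#' @param status_params True status-model parameters
#'   ([default_status_params()] by default).
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L,
                               lon_range = c(-70, -60), lat_range = c(-10, 0),
                               dlon = 0.5,
                               baseline_decade = c(1980L, 1989L),
                               recent_decade = c(2010L, 2019L),
                               base_temp = 24, lat_gradient = -0.2,
                               seasonal_amp = 4, warming_trend = 0.3,
                               ar_phi = 0.7, ar_sd = 2,
                               spei_trend_per_decade = -0.2, spei_phi = 0.5,
                               n_species = 300L,
                               area_range_deg2 = c(0.25, 25),
                               disjunct_prob = 0.2, blob_prob = 0.3,
                               n_families = 15L,
                               status_params = default_status_params()) {
  stopifnot(abs(ar_phi) < 1, abs(spei_phi) < 1, n_species >= 1L,
            area_range_deg2[1] > 0, area_range_deg2[2] >= area_range_deg2[1])
  structure(list(seed = as.integer(seed), lon_range = lon_range,
                 lat_range = lat_range, dlon = dlon,
                 baseline_decade = as.integer(baseline_decade),
                 recent_decade = as.integer(recent_decade),
                 base_temp = base_temp, lat_gradient = lat_gradient,
                 seasonal_amp = seasonal_amp, warming_trend = warming_trend,
                 ar_phi = ar_phi, ar_sd = ar_sd,
                 spei_trend_per_decade = spei_trend_per_decade,
                 spei_phi = spei_phi,
                 n_species = as.integer(n_species),
                 area_range_deg2 = area_range_deg2,
                 disjunct_prob = disjunct_prob, blob_prob = blob_prob,
                 n_families = as.integer(n_families),
                 status_params = status_params),
            class = "synthetic_scenario")
}

scenario_grid <- function(scenario) {
  grid_from_extent(scenario$lon_range, scenario$lat_range, scenario$dlon)
}

# Mean-shift of the recent-decade SPEI implied by the per-decade trend.
spei_recent_shift <- function(scenario) {
  gap <- (mean(scenario$recent_decade) - mean(scenario$baseline_decade)) / 10
  scenario$spei_trend_per_decade * gap
}

#' Generate a daily temperature cube
#'
#' Per cell: climatological mean (base temperature plus a latitude
#' gradient plus a fixed cell effect), a seasonal sinusoid, a linear
#' warming trend anchored at the baseline start, and AR(1) daily noise.
#'
#' @param scenario A [synthetic_scenario()].
#' @param period `"baseline"`, `"recent"` or a length-2 year range.
#' @return A [temperature_cube()] spanning the period, gap-free.
#' @export
gen_temperature_cube <- function(scenario, period = "baseline") {
  years <- period_years(scenario, period)
  grid <- scenario_grid(scenario)
  dates <- seq(as.Date(sprintf("%d-01-01", years[1])),
               as.Date(sprintf("%d-12-31", years[2])), by = "day")
  nd <- dim_grid(grid); ncell <- nd[1] * nd[2]; nt <- length(dates)

  # the per-cell climatology is a fixed property of the scenario: draw it
  # from a period-independent stream so both decades share it exactly
  set.seed(scenario$seed + 505L)
  cell_lat <- rep(grid$lat, each = nd[1])
  mid_lat <- mean(scenario$lat_range)
  cell_mean <- scenario$base_temp +
    scenario$lat_gradient * abs(cell_lat - mid_lat) +
    stats::rnorm(ncell, 0, 0.5)
  set.seed(scenario$seed + 101L * years[1])
  doy <- as.integer(format(dates, "%j"))
  hemis <- if (mid_lat < 0) pi else 0
  season <- scenario$seasonal_amp * sin(2 * pi * doy / 365.25 - pi / 2 + hemis)
  frac_year <- years[1] + (seq_len(nt) - 1L) / 365.25
  trend <- scenario$warming_trend * (frac_year - scenario$baseline_decade[1]) / 10

  eps <- matrix(stats::rnorm(nt * ncell, 0,
                             scenario$ar_sd * sqrt(1 - scenario$ar_phi^2)),
                nt, ncell)
  noise <- stats::filter(eps, scenario$ar_phi, method = "recursive")
  M <- noise + (season + trend) + rep(cell_mean, each = nt)
  values <- aperm(array(as.numeric(M), c(nt, nd[1], nd[2])), c(2, 3, 1))
  temperature_cube(grid, dates, values)
}

period_years <- function(scenario, period) {
  if (is.character(period))
    switch(period,
           baseline = scenario$baseline_decade,
           recent = scenario$recent_decade,
           stop("unknown period", call. = FALSE))
  else as.integer(period)
}

#' Generate a monthly SPEI cube
#'
#' Standard-normal AR(1) marginals per cell; the recent decade's mean is
#' shifted downward by the drying trend times the decade gap (a drying
#' climate produces more months below the severe-drought cutoff).
#'
#' @param scenario A [synthetic_scenario()].
#' @param period `"baseline"`, `"recent"`, `"both"` or a year range;
#'   `"both"` spans baseline through recent in one gap-free cube.
#' @return A [spei_cube()].
#' @export
gen_spei_cube <- function(scenario, period = "both") {
  years <- if (identical(period, "both"))
    c(scenario$baseline_decade[1], scenario$recent_decade[2])
  else period_years(scenario, period)
  grid <- scenario_grid(scenario)
  months <- seq(as.Date(sprintf("%d-01-01", years[1])),
                as.Date(sprintf("%d-12-01", years[2])), by = "month")
  nd <- dim_grid(grid); ncell <- nd[1] * nd[2]; nt <- length(months)

  set.seed(scenario$seed + 202L)
  eps <- matrix(stats::rnorm(nt * ncell, 0, sqrt(1 - scenario$spei_phi^2)),
                nt, ncell)
  z <- stats::filter(eps, scenario$spei_phi, method = "recursive")
  yr <- as.integer(format(months, "%Y"))
  shift <- ifelse(yr >= scenario$recent_decade[1] &
                    yr <= scenario$recent_decade[2],
                  spei_recent_shift(scenario), 0)
  M <- z + shift
  values <- aperm(array(as.numeric(M), c(nt, nd[1], nd[2])), c(2, 3, 1))
  spei_cube(grid, months, values)
}

#' Generate species ranges with taxonomy
#'
#' Range areas are log-uniform between the configured bounds (planar
#' degree^2). Each species is a rectangle or a convex blob (scaled to its
#' target area); with the configured probability it is split into 2-3
#' disjunct parts placed without mutual overlap. All parts lie inside the
#' scenario extent. Families are assigned with heavy-tailed sizes within
#' three orders mimicking a real species pool.
#'
#' @param scenario A [synthetic_scenario()].
#' @return List with `ranges` (list of [species_range()]) and `taxonomy`
#'   (data frame `species_id`, `order`, `family`, `genus`).
#' @export
gen_ranges <- function(scenario) {
  set.seed(scenario$seed + 303L)
  n <- scenario$n_species
  lo <- log(scenario$area_range_deg2[1]); hi <- log(scenario$area_range_deg2[2])
  areas <- exp(stats::runif(n, lo, hi))
  orders <- sample(c("Anura", "Caudata", "Gymnophiona"), n, replace = TRUE,
                   prob = c(0.880, 0.0965, 0.0235))
  fam_w <- 1 / seq_len(scenario$n_families)
  families <- paste0("family_", sample(scenario$n_families, n, replace = TRUE,
                                       prob = fam_w / sum(fam_w)))
  genera <- paste0("genus_", sample(3L * scenario$n_families, n, replace = TRUE))
  ranges <- vector("list", n)
  for (s in seq_len(n)) {
    nparts <- if (stats::runif(1) < scenario$disjunct_prob) sample(2:3, 1) else 1L
    wts <- stats::runif(nparts, 0.5, 1); wts <- wts / sum(wts)
    parts <- list(); tries <- 0L
    while (length(parts) < nparts && tries < 50L) {
      tries <- tries + 1L
      part <- place_part(areas[s] * wts[length(parts) + 1L], scenario)
      if (is.null(part)) next
      bb <- ring_bbox(part)
      clash <- any(vapply(parts, function(p) bbox_overlap(ring_bbox(p), bb),
                          logical(1)))
      if (!clash) parts <- c(parts, list(part))
    }
    if (!length(parts)) parts <- list(place_part(areas[s], scenario, force = TRUE))
    ranges[[s]] <- species_range(sprintf("species_%03d", s), parts,
                                 order = orders[s], family = families[s],
                                 genus = genera[s])
  }
  taxonomy <- data.frame(species_id = vapply(ranges, `[[`, character(1), "species_id"),
                         order = orders, family = families, genus = genera)
  list(ranges = ranges, taxonomy = taxonomy)
}

# One rectangular or convex-blob part of the requested planar area (deg^2),
# uniformly placed inside the scenario extent; NULL when it does not fit.
place_part <- function(area, scenario, force = FALSE) {
  lw <- diff(scenario$lon_range); lh <- diff(scenario$lat_range)
  aspect <- stats::runif(1, 0.5, 2)
  w <- min(sqrt(area * aspect), lw * 0.95)
  h <- area / w
  if (h > lh * 0.95) { h <- lh * 0.95; w <- area / h }
  if (w > lw * 0.95 || h > lh * 0.95) {
    if (!force) return(NULL)
    # domain smaller than the requested area: shrink to the largest fit
    w <- min(w, lw * 0.95); h <- min(h, lh * 0.95)
  }
  x0 <- stats::runif(1, scenario$lon_range[1], scenario$lon_range[2] - w)
  y0 <- stats::runif(1, scenario$lat_range[1], scenario$lat_range[2] - h)
  rect <- cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
  if (stats::runif(1) >= scenario$blob_prob) return(rect)
  # convex blob: hull of random points in the rectangle, rescaled about its
  # centroid to the target planar area, then clamped to the extent
  pts <- cbind(stats::runif(12, x0, x0 + w), stats::runif(12, y0, y0 + h))
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  cx <- mean(hull[, 1]); cy <- mean(hull[, 2])
  a0 <- planar_ring_area(hull)
  f <- sqrt(area / a0)
  hull <- cbind(cx + (hull[, 1] - cx) * f, cy + (hull[, 2] - cy) * f)
  hull[, 1] <- pmin(pmax(hull[, 1], scenario$lon_range[1]), scenario$lon_range[2])
  hull[, 2] <- pmin(pmax(hull[, 2], scenario$lat_range[1]), scenario$lat_range[2])
  tryCatch(clean_ring(hull), error = function(e) rect)
}

planar_ring_area <- function(ring) {
  n <- nrow(ring); nxt <- c(2:n, 1L)
  abs(sum(ring[, 1] * ring[nxt, 2] - ring[nxt, 1] * ring[, 2])) / 2
}

#' Simulate Red List status changes from exposures
#'
#' Samples each species' outcome (`no_change`, `uplisted`, `downlisted`)
#' from the multinomial logit whose linear predictors are
#' `log(intercept_odds) + sum(log(OR) * exposure)` per non-reference
#' outcome, with `no_change` fixed at 0.
#'
#' @param exposures Data frame with `species_id`, `heat_exposure`,
#'   `drought_exposure`, `cold_exposure` in \[0, 1\].
#' @param params True parameters as in [default_status_params()].
#' @param seed Integer seed.
#' @param period Period label stored in the output.
#' @return Data frame `species_id`, `period`, `outcome`, and the three
#'   exposure columns.
#' @export
gen_status_changes <- function(exposures, params = default_status_params(),
                               seed = 1L, period = "2004-2022") {
  stopifnot(all(c("heat_exposure", "drought_exposure", "cold_exposure")
                %in% names(exposures)))
  X <- as.matrix(cbind(1, exposures[c("heat_exposure", "drought_exposure",
                                      "cold_exposure")]))
  eta <- cbind(0,
               X %*% log(unname(params$uplisted)),
               X %*% log(unname(params$downlisted)))
  colnames(eta) <- c("no_change", "uplisted", "downlisted")
  P <- exp(eta) / rowSums(exp(eta))
  set.seed(seed)
  u <- stats::runif(nrow(P))
  cum <- t(apply(P, 1, cumsum))
  pick <- 1L + rowSums(u > cum[, -ncol(cum), drop = FALSE])
  data.frame(species_id = exposures$species_id, period = period,
             outcome = colnames(eta)[pick],
             exposures[c("heat_exposure", "drought_exposure", "cold_exposure")])
}

#' Pivot an exposure table to one row per species
#'
#' @param exposure Long exposure table from [exposure_table()].
#' @return Data frame `species_id`, `heat_exposure`, `drought_exposure`,
#'   `cold_exposure` (proportions; 0 where a class is absent).
#' @export
exposure_wide <- function(exposure) {
  map <- c(heat_wave = "heat_exposure", drought = "drought_exposure",
           cold_spell = "cold_exposure")
  ids <- unique(exposure$species_id)
  out <- data.frame(species_id = ids, heat_exposure = 0, drought_exposure = 0,
                    cold_exposure = 0)
  for (cls in names(map)) {
    sub <- exposure[exposure$event_class == cls, ]
    out[[map[[cls]]]] <- sub$proportion[match(ids, sub$species_id)]
    out[[map[[cls]]]][is.na(out[[map[[cls]]]])] <- 0
  }
  out
}

#' Run the full pipeline on a synthetic scenario
#'
#' Generates temperature and SPEI cubes, detects events, builds decadal
#' difference fields and hazard layers (clipped to the species footprint
#' mask), computes per-species exposure, aggregates by taxon and grid, and
#' fits the status model to outcomes simulated under the scenario's true
#' parameters.
#'
#' @param scenario A [synthetic_scenario()].
#' @param config An [analysis_config()].
#' @return Named list with every intermediate product (`cubes`, `counts`,
#'   `diffs`, `mask`, `layers`, `ranges`, `taxonomy`, `exposure`,
#'   `exposure_wide`, `status`, `fit`, `grid_summary`, `taxon`, `multi`).
#' @export
run_synthetic_pipeline <- function(scenario = synthetic_scenario(),
                                   config = analysis_config(
                                     baseline_decade = scenario$baseline_decade,
                                     recent_decade = scenario$recent_decade)) {
  gen <- gen_ranges(scenario)
  grid <- scenario_grid(scenario)
  mask <- region_mask_from_ranges(gen$ranges, grid)

  diffs <- list()
  cube_b <- gen_temperature_cube(scenario, "baseline")
  cube_r <- gen_temperature_cube(scenario, "recent")
  for (cls in c("heat_wave", "cold_spell")) {
    dirn <- if (cls == "heat_wave") "above" else "below"
    q <- if (cls == "heat_wave") config$heat_q else config$cold_q
    thr <- compute_percentile_threshold(cube_b, q,
             range(cube_b$dates),
             calendar_window_days = config$calendar_window_days)
    cnt_b <- monthly_event_counts(cube_b, thr, dirn, config$run_length_days,
                                  config$count_rule, event_class = cls)
    cnt_r <- monthly_event_counts(cube_r, thr, dirn, config$run_length_days,
                                  config$count_rule, event_class = cls)
    diffs[[cls]] <- difference_field(decadal_count(cnt_r, config$recent_decade),
                                     decadal_count(cnt_b, config$baseline_decade))
  }
  spei <- gen_spei_cube(scenario, "both")
  dr <- drought_event_mask(spei, config$spei_cutoff)
  diffs$drought <- difference_field(decadal_count(dr, config$recent_decade),
                                    decadal_count(dr, config$baseline_decade))

  layers <- lapply(diffs, build_hazard_layer, mask = mask, config = config)
  exposure <- exposure_table(gen$ranges, layers, diffs, config$exposure_cutoff)
  wide <- exposure_wide(exposure)
  status <- gen_status_changes(wide, scenario$status_params,
                               seed = scenario$seed + 404L)
  # at small n a simulated outcome level can be absent; the fit is then
  # uninformative and reported as NULL rather than aborting the pipeline
  fit <- tryCatch(suppressWarnings(fit_status_model(status)),
                  error = function(e) {
                    message("status model not fitted: ", conditionMessage(e))
                    NULL
                  })
  list(grid = grid,
       counts_baseline = NULL,
       diffs = diffs, mask = mask, layers = layers,
       ranges = gen$ranges, taxonomy = gen$taxonomy,
       exposure = exposure, exposure_wide = wide, status = status, fit = fit,
       grid_summary = exposed_grid(gen$ranges, exposure,
                                   config$aggregation_cell_degrees),
       taxon = taxon_summary(exposure, gen$taxonomy, "family"),
       multi = multi_exposure(exposure))
}
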