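#' Overlap of a species range with a hazard layer
#'
#' Computes the spherical area of intersection between a range and the
#' cells of a binary hazard layer. For internal consistency the total
#' range area is computed the same way against the full grid footprint
#' (every cell, in or out of the layer), so the proportion is exactly the
#' layer-cell share of the gridded range area and lies in \[0, 1\].
#' Overlapping multipart pieces are resolved to their union before areas
#' are summed.
#'
#' @param range A [species_range()].
#' @param layer A [hazard_layer()][binarize].
#' @return A list with `overlap_km2`, `total_km2`, `proportion`.
#' @export
overlap_proportion <- function(range, layer) {
  stopifnot(inherits(range, "species_range"), inherits(layer, "hazard_layer"))
  cells <- range_cell_areas(range, layer$grid)
  total <- sum(cells$area_km2)
  if (total <= 0)
    stop(sprintf("range %s has zero area on the layer grid", range$species_id),
         call. = FALSE)
  inside <- layer$inside[cbind(cells$i, cells$j)]
  overlap <- sum(cells$area_km2[inside])
  list(overlap_km2 = overlap, total_km2 = total,
       proportion = min(1, overlap / total))
}

#' Exposure classification
#'
#' A species is exposed when its overlap proportion is strictly greater
#' than the cutoff (default 0.5, i.e. more than half of the range).
#'
#' @param proportion Overlap proportion in \[0, 1\].
#' @param cutoff Strict cutoff in (0, 1).
#' @return Logical.
#' @export
classify_exposed <- function(proportion, cutoff = 0.5) {
  stopifnot(all(proportion >= 0 & proportion <= 1, na.rm = TRUE),
            cutoff > 0, cutoff < 1)
  proportion > cutoff
}

#' Excess events within a species range (zonal statistics)
#'
#' Summarizes the decadal difference-in-counts field over the grid cells a
#' range intersects: plain mean, sum, and overlap-area-weighted mean.
#' Masked (`NA`) cells are excluded; if the range touches no unmasked cell
#' the summaries are `NA` and the record is flagged.
#'
#' @param range A [species_range()].
#' @param diff A [difference_field()].
#' @param rule Cell-membership rule: `"area"` (any positive-area overlap,
#'   default) or `"center"` (cell centre inside the range).
#' @return A list with `mean`, `sum`, `weighted_mean`, `n_cells`,
#'   `no_cells` flag.
#' @export
excess_events_in_range <- function(range, diff, rule = c("area", "center")) {
  rule <- match.arg(rule)
  stopifnot(inherits(range, "species_range"), inherits(diff, "difference_field"))
  if (rule == "area") {
    cells <- range_cell_areas(range, diff$grid)
    v <- diff$values[cbind(cells$i, cells$j)]
    w <- cells$area_km2
  } else {
    ctr <- expand.grid(i = seq_along(diff$grid$lon), j = seq_along(diff$grid$lat))
    hit <- point_in_parts(diff$grid$lon[ctr$i], diff$grid$lat[ctr$j], range$parts)
    cells <- ctr[hit, , drop = FALSE]
    v <- diff$values[cbind(cells$i, cells$j)]
    w <- cell_area_km2(diff$grid, cells$j)
  }
  ok <- !is.na(v)
  if (!any(ok))
    return(list(mean = NA_real_, sum = NA_real_, weighted_mean = NA_real_,
                n_cells = 0L, no_cells = TRUE))
  list(mean = mean(v[ok]), sum = sum(v[ok]),
       weighted_mean = sum(v[ok] * w[ok]) / sum(w[ok]),
       n_cells = sum(ok), no_cells = FALSE)
}

#' Per-species exposure table across event classes
#'
#' Runs [overlap_proportion()], [classify_exposed()] and
#' [excess_events_in_range()] for every species and every hazard layer and
#' assembles the canonical exposure record table (one row per species x
#' event class).
#'
#' @param ranges List of [species_range()] objects.
#' @param layers Named list of `hazard_layer` objects (names are event
#'   classes).
#' @param diffs Optional named list of [difference_field()] objects matching
#'   `layers`, for the excess-event summaries.
#' @param cutoff Exposure cutoff (strict), default 0.5.
#' @return A data frame with columns `species_id`, `event_class`,
#'   `overlap_km2`, `total_km2`, `proportion`, `exposed`, `excess_mean`,
#'   `excess_sum`.
#' @export
exposure_table <- function(ranges, layers, diffs = NULL, cutoff = 0.5) {
  stopifnot(length(layers) >= 1L, !is.null(names(layers)))
  rows <- vector("list", length(ranges) * length(layers))
  k <- 0L
  for (rng in ranges) for (cls in names(layers)) {
    ov <- overlap_proportion(rng, layers[[cls]])
    ex <- if (!is.null(diffs) && !is.null(diffs[[cls]]))
      excess_events_in_range(rng, diffs[[cls]])
    else list(mean = NA_real_, sum = NA_real_)
    k <- k + 1L
    rows[[k]] <- data.frame(species_id = rng$species_id, event_class = cls,
                            overlap_km2 = ov$overlap_km2,
                            total_km2 = ov$total_km2,
                            proportion = ov$proportion,
                            exposed = classify_exposed(ov$proportion, cutoff),
                            excess_mean = ex$mean, excess_sum = ex$sum)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
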