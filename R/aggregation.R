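#' Species richness matrix on a grid
#'
#' Counts, per grid cell, the species whose range has a positive-area
#' intersection with that cell (not a centroid rule, so small-ranged
#' species are never lost).
#'
#' @param ranges List of [species_range()] objects.
#' @param grid A [grid_spec()].
#' @return Integer `nlon x nlat` matrix.
#' @export
richness_matrix <- function(ranges, grid) {
  nd <- dim_grid(grid)
  rich <- matrix(0L, nd[1], nd[2])
  for (rng in ranges) {
    cells <- range_cell_areas(rng, grid)
    if (nrow(cells))
      rich[cbind(cells$i, cells$j)] <- rich[cbind(cells$i, cells$j)] + 1L
  }
  rich
}

summary_grid_for <- function(ranges, cell_degrees, extent = NULL) {
  if (inherits(cell_degrees, "grid_spec")) return(cell_degrees)
  if (is.null(extent)) {
    bbs <- do.call(rbind, lapply(ranges, function(r)
      do.call(rbind, lapply(r$parts, function(p) ring_bbox(p)))))
    cd <- cell_degrees
    extent <- list(lon = c(floor(min(bbs[, "xmin"]) / cd) * cd,
                           ceiling(max(bbs[, "xmax"]) / cd) * cd),
                   lat = c(floor(min(bbs[, "ymin"]) / cd) * cd,
                           ceiling(max(bbs[, "ymax"]) / cd) * cd))
  }
  grid_from_extent(extent$lon, extent$lat, cell_degrees)
}

#' Gridded species richness
#'
#' @param ranges List of [species_range()] objects.
#' @param cell_degrees Summary cell size in degrees (default 2), or a
#'   [grid_spec()] to use directly.
#' @param extent Optional list with `lon` and `lat` length-2 extents;
#'   default snaps to the ranges' bounding box.
#' @return An object of class `summary_grid` with a `richness` matrix.
#' @export
richness_grid <- function(ranges, cell_degrees = 2, extent = NULL) {
  grid <- summary_grid_for(ranges, cell_degrees, extent)
  structure(list(grid = grid, richness = richness_matrix(ranges, grid)),
            class = "summary_grid")
}

#' Gridded exposed-species counts and proportions
#'
#' Filters the ranges by exposure status per event class, grids the counts
#' with the same positive-area intersection rule as [richness_grid()], and
#' divides by cell richness.
#'
#' @param ranges List of [species_range()] objects.
#' @param exposure Exposure table from [exposure_table()].
#' @param cell_degrees Summary cell size in degrees, or a [grid_spec()].
#' @param extent Optional extent (see [richness_grid()]).
#' @return A `summary_grid` with `richness`, and per event class matrices
#'   in `exposed_count` and `exposed_proportion` (proportion `NA` where
#'   richness is 0).
#' @export
exposed_grid <- function(ranges, exposure, cell_degrees = 2, extent = NULL) {
  grid <- summary_grid_for(ranges, cell_degrees, extent)
  rich <- richness_matrix(ranges, grid)
  ids <- vapply(ranges, function(r) r$species_id, character(1))
  classes <- unique(exposure$event_class)
  counts <- props <- stats::setNames(vector("list", length(classes)), classes)
  for (cls in classes) {
    ex_ids <- exposure$species_id[exposure$event_class == cls & exposure$exposed]
    sub <- ranges[ids %in% ex_ids]
    cnt <- richness_matrix(sub, grid)
    if (any(cnt > rich))
      stop("internal error: exposed count exceeds richness", call. = FALSE)
    counts[[cls]] <- cnt
    p <- cnt / rich
    p[rich == 0L] <- NA_real_
    props[[cls]] <- p
  }
  structure(list(grid = grid, richness = rich, exposed_count = counts,
                 exposed_proportion = props),
            class = "summary_grid")
}

#' Exposure tallies by taxonomic group
#'
#' @param exposure Exposure table from [exposure_table()] (or any data
#'   frame with `species_id`, `event_class`, `exposed`).
#' @param taxonomy Data frame with `species_id` and the taxonomy columns
#'   (`order`, `family`, `genus`).
#' @param level One of `"order"`, `"family"`, `"genus"`.
#' @return Data frame with `level`, `taxon`, `event_class`, `n_species`,
#'   `n_exposed`, `percent_exposed` (full precision; round only for
#'   display).
#' @export
taxon_summary <- function(exposure, taxonomy, level = c("order", "family", "genus")) {
  level <- match.arg(level)
  lab <- taxonomy[[level]][match(exposure$species_id, taxonomy$species_id)]
  if (anyNA(lab)) {
    warning(sprintf("%d records without a %s label collected under UNASSIGNED",
                    sum(is.na(lab)), level), call. = FALSE)
    lab[is.na(lab)] <- "UNASSIGNED"
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(exposure)),
                                     list(lab, exposure$event_class), drop = TRUE),
    function(idx) {
      data.frame(level = level, taxon = lab[idx[1]],
                 event_class = exposure$event_class[idx[1]],
                 n_species = length(unique(exposure$species_id[idx])),
                 n_exposed = length(unique(exposure$species_id[idx][exposure$exposed[idx]])))
    }))
  out$percent_exposed <- 100 * out$n_exposed / out$n_species
  rownames(out) <- NULL
  out[order(out$event_class, out$taxon), ]
}

#' Exposed-species counts per country
#'
#' A species counts once in every country its range intersects with
#' positive area (a range straddling a border counts in both countries).
#' Country polygons must be convex per part; non-convex countries should be
#' supplied pre-decomposed into convex pieces.
#'
#' @param ranges List of [species_range()] objects.
#' @param countries Named list; each element a 2-column (lon, lat) matrix
#'   or a list of such convex parts.
#' @param exposure Optional exposure table; when given, counts are reported
#'   per event class over exposed species only, otherwise total richness
#'   per country.
#' @return Data frame `country`, `event_class` (or `"all"`), `n_species`.
#' @export
country_summary <- function(ranges, countries, exposure = NULL) {
  stopifnot(!is.null(names(countries)))
  countries <- lapply(countries, function(cc) if (is.matrix(cc)) list(cc) else cc)
  intersects <- function(rng, parts) {
    for (cp in parts) for (rp in rng$parts) {
      if (!bbox_overlap(ring_bbox(rp), ring_bbox(cp))) next
      piece <- clip_ring_convex(rp, cp)
      if (nrow(piece) >= 3L && ring_area_km2(piece) > 1e-9) return(TRUE)
    }
    FALSE
  }
  ids <- vapply(ranges, function(r) r$species_id, character(1))
  groups <- if (is.null(exposure)) list(all = ids) else {
    sp <- split(exposure$species_id[exposure$exposed],
                exposure$event_class[exposure$exposed])
    lapply(sp, unique)
  }
  rows <- list()
  for (cls in names(groups)) {
    sub <- ranges[ids %in% groups[[cls]]]
    for (cn in names(countries)) {
      n <- sum(vapply(sub, intersects, logical(1), parts = countries[[cn]]))
      rows[[length(rows) + 1L]] <- data.frame(country = cn, event_class = cls,
                                              n_species = n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multi-exposure combinations
#'
#' Partitions species by the exact set of event classes they are exposed
#' to and reports combination counts plus the share of species exposed to
#' two or more classes.
#'
#' @param exposure Exposure table with one record per species x event
#'   class; duplicates are an error.
#' @return A list with `combinations` (data frame `combination`,
#'   `n_species`), `n_species` total, `n_multi`, `percent_multi`.
#' @export
multi_exposure <- function(exposure) {
  key <- paste(exposure$species_id, exposure$event_class)
  if (anyDuplicated(key))
    stop("duplicate (species, event_class) records", call. = FALSE)
  sets <- lapply(split(exposure, exposure$species_id), function(d)
    sort(d$event_class[d$exposed]))
  combo <- vapply(sets, function(s) if (length(s)) paste(s, collapse = "+") else "none",
                  character(1))
  tab <- as.data.frame(table(combination = combo), stringsAsFactors = FALSE)
  names(tab)[2] <- "n_species"
  nsp <- length(sets)
  nmulti <- sum(vapply(sets, length, integer(1)) >= 2L)
  stopifnot(sum(tab$n_species) == nsp)
  list(combinations = tab, n_species = nsp, n_multi = nmulti,
       percent_multi = 100 * nmulti / nsp)
}
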