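#' Decadal event count
#'
#' Sums monthly event counts cell-wise over a decade. The decade must be
#' fully covered by the input months (all 120 of them, or more generally
#' every month of the year range); partial coverage is an error, never a
#' silent truncation.
#'
#' @param counts An [event_counts()] object.
#' @param decade Length-2 integer year range, e.g. `c(2010, 2019)`.
#' @return An object of class `decadal_count` with an `nlon x nlat` integer
#'   `values` matrix (`NA` on masked cells).
#' @export
decadal_count <- function(counts, decade) {
  stopifnot(inherits(counts, "event_counts"), length(decade) == 2L)
  decade <- as.integer(decade)
  want <- seq(as.Date(sprintf("%d-01-01", decade[1])),
              as.Date(sprintf("%d-12-01", decade[2])), by = "month")
  sel <- match(month_index(want), month_index(counts$months))
  if (anyNA(sel))
    stop(sprintf("months do not fully cover %d-%d (%d of %d present)",
                 decade[1], decade[2], sum(!is.na(sel)), length(want)), call. = FALSE)
  vals <- apply(counts$counts[, , sel, drop = FALSE], c(1, 2), sum)
  vals[!counts$mask] <- NA_integer_
  structure(list(grid = counts$grid, decade = decade, values = vals,
                 event_class = counts$event_class),
            class = "decadal_count")
}

#' Difference in decadal event counts (recent minus baseline)
#'
#' @param recent,baseline `decadal_count` objects on the same grid and for
#'   the same event class.
#' @return An object of class `difference_field`; `values` is the exact
#'   integer cell-wise difference, `NA` where either input is masked.
#' @export
difference_field <- function(recent, baseline) {
  stopifnot(inherits(recent, "decadal_count"), inherits(baseline, "decadal_count"))
  if (!grids_identical(recent$grid, baseline$grid))
    stop("grids differ", call. = FALSE)
  if (recent$event_class != baseline$event_class)
    stop("event classes differ", call. = FALSE)
  structure(list(grid = recent$grid, values = recent$values - baseline$values,
                 event_class = recent$event_class,
                 recent_decade = recent$decade, baseline_decade = baseline$decade),
            class = "difference_field")
}

#' Region mask on a grid
#'
#' @param grid A [grid_spec()].
#' @param inside Logical `nlon x nlat` matrix with at least one `TRUE` cell.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(grid, inside) {
  nd <- dim_grid(grid)
  stopifnot(is.logical(inside), all(dim(inside) == nd))
  if (!any(inside)) stop("region mask has no inside cell", call. = FALSE)
  structure(list(grid = grid, inside = inside), class = "region_mask")
}

#' Region mask from the union footprint of species ranges
#'
#' A cell is inside the mask when at least one species range has a
#' positive-area intersection with it — the gridded footprint of the whole
#' species set (e.g. the global distribution of a class).
#'
#' @param ranges List of [species_range()] objects.
#' @param grid A [grid_spec()].
#' @return A [region_mask()].
#' @export
region_mask_from_ranges <- function(ranges, grid) {
  rich <- richness_matrix(ranges, grid)
  region_mask(grid, rich > 0L)
}

#' Percentile of a difference field over a region
#'
#' Linear-interpolation percentile of the difference-in-counts values,
#' computed over unmasked cells inside the region only.
#'
#' @param diff A [difference_field()].
#' @param mask A [region_mask()] on the same grid.
#' @param q Percentile level in \[0, 100\].
#' @return Scalar threshold (unrounded).
#' @examples
#' g <- grid_from_extent(c(0, 2.5), c(0, 0.5), 0.5)
#' d <- structure(list(grid = g, values = matrix(c(0, 10, 20, 30, 40), 5, 1),
#'                     event_class = "heat_wave"), class = "difference_field")
#' m <- region_mask(g, matrix(TRUE, 5, 1))
#' field_percentile(d, m, 80)  # 32
#' @export
field_percentile <- function(diff, mask, q) {
  stopifnot(inherits(diff, "difference_field"), inherits(mask, "region_mask"),
            q >= 0, q <= 100)
  if (!grids_identical(diff$grid, mask$grid)) stop("grids differ", call. = FALSE)
  v <- diff$values[mask$inside]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no unmasked in-region cells", call. = FALSE)
  stats::quantile(v, q / 100, names = FALSE, type = 7)
}

#' Binarization rules for hazard layers
#'
#' `ge_threshold(t)` keeps cells with difference `>= t` (the heat and
#' drought rule, thresholded at a percentile of the in-mask differences);
#' `increase_only()` keeps cells with a strictly positive difference (the
#' cold-spell rule), or `>= 0` when `include_zero = TRUE`.
#'
#' @param t Scalar threshold (stored unrounded).
#' @param include_zero Keep zero-change cells too.
#' @return A rule object for [binarize()].
#' @export
ge_threshold <- function(t) {
  stopifnot(is.finite(t))
  structure(list(type = "ge_threshold", t = t), class = "binarize_rule")
}

#' @rdname ge_threshold
#' @export
increase_only <- function(include_zero = FALSE) {
  structure(list(type = "increase_only", include_zero = isTRUE(include_zero)),
            class = "binarize_rule")
}

#' Binary hazard layer from a difference field
#'
#' @param diff A [difference_field()].
#' @param mask A [region_mask()]; cells outside are never in the layer.
#' @param rule A [ge_threshold()] or [increase_only()] rule.
#' @return An object of class `hazard_layer` with logical `inside` matrix
#'   and the rule recorded as metadata.
#' @export
binarize <- function(diff, mask, rule) {
  stopifnot(inherits(diff, "difference_field"), inherits(mask, "region_mask"),
            inherits(rule, "binarize_rule"))
  if (!grids_identical(diff$grid, mask$grid)) stop("grids differ", call. = FALSE)
  v <- diff$values
  keep <- switch(rule$type,
                 ge_threshold = v >= rule$t,
                 increase_only = if (rule$include_zero) v >= 0 else v > 0)
  keep[is.na(keep)] <- FALSE
  structure(list(grid = diff$grid, inside = keep & mask$inside,
                 event_class = diff$event_class,
                 threshold_value = if (rule$type == "ge_threshold") rule$t else
                   if (rule$include_zero) 0 else .Machine$double.eps,
                 threshold_rule = rule),
            class = "hazard_layer")
}

#' Build a hazard layer per event class under the standard rules
#'
#' Heat-wave and drought layers are thresholded at the configured
#' percentile of the in-mask difference-in-counts; cold-spell layers keep
#' increases only (the percentile rule would admit negative changes under a
#' general decline in cold spells).
#'
#' @param diff A [difference_field()].
#' @param mask A [region_mask()].
#' @param config An [analysis_config()].
#' @return A `hazard_layer`; for percentile-ruled classes the computed
#'   threshold is recorded in `threshold_value`.
#' @export
build_hazard_layer <- function(diff, mask, config = analysis_config()) {
  rule <- if (diff$event_class == "cold_spell") {
    increase_only(config$cold_include_zero)
  } else {
    ge_threshold(field_percentile(diff, mask, config$layer_percentile))
  }
  binarize(diff, mask, rule)
}

#' @export
print.hazard_layer <- function(x, ...) {
  cat(sprintf("<hazard_layer: %s> %d of %d cells inside (rule: %s)\n",
              x$event_class, sum(x$inside), length(x$inside),
              x$threshold_rule$type))
  invisible(x)
}
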