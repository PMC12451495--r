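#' Gridded daily temperature cube
#'
#' @param grid A [grid_spec()].
#' @param dates `Date` vector of consecutive calendar days (gap-free,
#'   strictly increasing).
#' @param values Numeric array `c(nlon, nlat, ndays)`, degrees Celsius;
#'   `NA` marks missing/masked values.
#' @return An object of class `temperature_cube`.
#' @export
temperature_cube <- function(grid, dates, values) {
  dates <- as.Date(dates)
  if (length(dates) < 1L || anyNA(dates)) stop("invalid dates", call. = FALSE)
  if (length(dates) > 1L && any(diff(as.integer(dates)) != 1L))
    stop("dates must be consecutive calendar days with no gaps", call. = FALSE)
  check_cube_dims(grid, values, length(dates))
  structure(list(grid = grid, dates = dates, values = values),
            class = "temperature_cube")
}

#' Gridded monthly SPEI cube
#'
#' Holds standardized (unitless, approximately standard-normal) SPEI values;
#' the package consumes SPEI as an input and never computes it from
#' precipitation or potential evapotranspiration.
#'
#' @param grid A [grid_spec()].
#' @param months `Date` vector of first-of-month dates, consecutive months.
#' @param values Numeric array `c(nlon, nlat, nmonths)`; `NA` = missing.
#' @return An object of class `spei_cube`.
#' @export
spei_cube <- function(grid, months, values) {
  months <- check_months(months)
  check_cube_dims(grid, values, length(months))
  big <- abs(values) >= 5
  if (any(big, na.rm = TRUE))
    warning(sprintf("%d SPEI values with |value| >= 5; inputs are expected on a standardized scale",
                    sum(big, na.rm = TRUE)), call. = FALSE)
  structure(list(grid = grid, months = months, values = values),
            class = "spei_cube")
}

#' Monthly extreme-event counts
#'
#' @param grid A [grid_spec()].
#' @param months `Date` vector of first-of-month dates, consecutive.
#' @param counts Integer array `c(nlon, nlat, nmonths)` of event counts.
#' @param event_class One of `"heat_wave"`, `"cold_spell"`, `"drought"`.
#' @param mask Logical `nlon x nlat` matrix; `FALSE` marks masked cells
#'   (counts are reported 0 there but flagged).
#' @return An object of class `event_counts`.
#' @export
event_counts <- function(grid, months, counts, event_class, mask = NULL) {
  event_class <- match.arg(event_class, c("heat_wave", "cold_spell", "drought"))
  months <- check_months(months)
  check_cube_dims(grid, counts, length(months))
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative", call. = FALSE)
  nd <- dim_grid(grid)
  if (is.null(mask)) mask <- matrix(TRUE, nd[1], nd[2])
  stopifnot(is.logical(mask), all(dim(mask) == nd))
  counts[rep(!mask, length(months))] <- 0L
  structure(list(grid = grid, months = months, counts = counts,
                 event_class = event_class, mask = mask),
            class = "event_counts")
}

check_months <- function(months) {
  months <- as.Date(months)
  if (length(months) < 1L || anyNA(months)) stop("invalid months", call. = FALSE)
  if (any(format(months, "%d") != "01"))
    stop("months must be first-of-month dates", call. = FALSE)
  if (length(months) > 1L) {
    idx <- month_index(months)
    if (any(diff(idx) != 1L)) stop("months must be consecutive", call. = FALSE)
  }
  months
}

month_index <- function(months) {
  as.integer(format(months, "%Y")) * 12L + as.integer(format(months, "%m"))
}

check_cube_dims <- function(grid, values, ntime) {
  nd <- dim_grid(grid)
  if (!is.array(values) || length(dim(values)) != 3L ||
      !all(dim(values) == c(nd[1], nd[2], ntime)))
    stop(sprintf("values must be an array with dim c(%d, %d, %d) [lon, lat, time]",
                 nd[1], nd[2], ntime), call. = FALSE)
  invisible(values)
}

#' @export
print.temperature_cube <- function(x, ...) {
  cat(sprintf("<temperature_cube> %d x %d cells, %d days (%s to %s)\n",
              length(x$grid$lon), length(x$grid$lat), length(x$dates),
              min(x$dates), max(x$dates)))
  invisible(x)
}

#' @export
print.spei_cube <- function(x, ...) {
  cat(sprintf("<spei_cube> %d x %d cells, %d months (%s to %s)\n",
              length(x$grid$lon), length(x$grid$lat), length(x$months),
              format(min(x$months), "%Y-%m"), format(max(x$months), "%Y-%m")))
  invisible(x)
}

#' @export
print.event_counts <- function(x, ...) {
  cat(sprintf("<event_counts: %s> %d x %d cells, %d months, total %d events\n",
              x$event_class, length(x$grid$lon), length(x$grid$lat),
              length(x$months), sum(x$counts, na.rm = TRUE)))
  invisible(x)
}
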