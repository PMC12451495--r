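#' Regular lon/lat grid specification
#'
#' Describes a regular, cell-centre registered longitude/latitude grid.
#' All gridded objects in the package (daily temperature cubes, SPEI cubes,
#' event-count stacks, hazard layers) carry one of these.
#'
#' @param lon Numeric vector of cell-centre longitudes, ascending, uniform
#'   spacing, in \[-180, 180).
#' @param lat Numeric vector of cell-centre latitudes, ascending, uniform
#'   spacing, in \[-90, 90\].
#' @param dlon,dlat Cell sizes in degrees; inferred from the axis spacing
#'   when omitted (required for single-cell axes).
#' @return An object of class `grid_spec` with elements `lon`, `lat`,
#'   `dlon`, `dlat`.
#' @examples
#' g <- grid_spec(seq(-69.75, -60.25, 0.5), seq(-9.75, -0.25, 0.5))
#' dim_grid(g)
#' @export
grid_spec <- function(lon, lat, dlon = NULL, dlat = NULL) {
  check_axis(lon, "lon", -180, 180, right_open = TRUE)
  check_axis(lat, "lat", -90, 90)
  if (is.null(dlon))
    dlon <- if (length(lon) > 1L) lon[2L] - lon[1L] else
      stop("'dlon' is required for a single-column grid", call. = FALSE)
  if (is.null(dlat))
    dlat <- if (length(lat) > 1L) lat[2L] - lat[1L] else
      stop("'dlat' is required for a single-row grid", call. = FALSE)
  if (length(lon) > 1L && abs(dlon - (lon[2L] - lon[1L])) > 1e-9)
    stop("'dlon' disagrees with the lon spacing", call. = FALSE)
  if (length(lat) > 1L && abs(dlat - (lat[2L] - lat[1L])) > 1e-9)
    stop("'dlat' disagrees with the lat spacing", call. = FALSE)
  structure(list(lon = as.numeric(lon), lat = as.numeric(lat),
                 dlon = dlon, dlat = dlat),
            class = "grid_spec")
}

check_axis <- function(x, name, lo, hi, right_open = FALSE) {
  if (length(x) < 1L || anyNA(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a non-empty numeric vector", name), call. = FALSE)
  if (length(x) > 1L) {
    d <- diff(x)
    if (any(d <= 0)) stop(sprintf("'%s' must be strictly ascending", name), call. = FALSE)
    if (max(d) - min(d) > 1e-9)
      stop(sprintf("'%s' spacing is not uniform", name), call. = FALSE)
  }
  if (min(x) < lo || (right_open && max(x) >= hi) || (!right_open && max(x) > hi))
    stop(sprintf("'%s' out of range [%g, %g%s", name, lo, hi,
                 if (right_open) ")" else "]"), call. = FALSE)
  invisible(x)
}

#' Construct a grid covering an extent
#'
#' @param lon_range,lat_range Length-2 numeric extents (cell edges).
#' @param dlon,dlat Cell sizes in degrees.
#' @return A [grid_spec()] whose cells tile the extent.
#' @export
grid_from_extent <- function(lon_range, lat_range, dlon, dlat = dlon) {
  nlon <- max(1L, round(diff(lon_range) / dlon))
  nlat <- max(1L, round(diff(lat_range) / dlat))
  grid_spec(lon_range[1] + (seq_len(nlon) - 0.5) * dlon,
            lat_range[1] + (seq_len(nlat) - 0.5) * dlat,
            dlon = dlon, dlat = dlat)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells (%.4g x %.4g deg), lon [%g, %g], lat [%g, %g]\n",
              length(x$lon), length(x$lat), x$dlon, x$dlat,
              min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  invisible(x)
}

#' Grid dimensions
#' @param grid A [grid_spec()].
#' @return Integer vector `c(nlon, nlat)`.
#' @export
dim_grid <- function(grid) c(length(grid$lon), length(grid$lat))

grids_identical <- function(a, b, tol = 1e-9) {
  length(a$lon) == length(b$lon) && length(a$lat) == length(b$lat) &&
    max(abs(a$lon - b$lon)) <= tol && max(abs(a$lat - b$lat)) <= tol
}

#' Edges of a grid cell
#' @keywords internal
#' @noRd
cell_bounds <- function(grid, i, j) {
  c(xmin = grid$lon[i] - grid$dlon / 2, xmax = grid$lon[i] + grid$dlon / 2,
    ymin = grid$lat[j] - grid$dlat / 2, ymax = grid$lat[j] + grid$dlat / 2)
}

#' Spherical area of grid cells
#'
#' Area of a lon/lat cell on a sphere of radius `R`:
#' `R^2 * dlon_rad * (sin(lat_top) - sin(lat_bottom))`. Equal for all cells
#' in a latitude band.
#'
#' @param grid A [grid_spec()].
#' @param lat_index Optional integer vector of latitude indices; default all.
#' @param R Earth radius in km (sphere).
#' @return Numeric vector of cell areas in km^2, one per requested latitude
#'   band.
#' @examples
#' g <- grid_from_extent(c(-1, 1), c(-1, 1), 0.5)
#' cell_area_km2(g)  # symmetric about the equator
#' @export
cell_area_km2 <- function(grid, lat_index = seq_along(grid$lat), R = 6371) {
  stopifnot(all(lat_index >= 1L), all(lat_index <= length(grid$lat)))
  lat <- grid$lat[lat_index]
  top <- (lat + grid$dlat / 2) * pi / 180
  bot <- (lat - grid$dlat / 2) * pi / 180
  R^2 * (grid$dlon * pi / 180) * (sin(top) - sin(bot))
}

#' Matrix of per-cell spherical areas
#' @inheritParams cell_area_km2
#' @return `nlon x nlat` matrix of areas in km^2.
#' @export
cell_area_matrix <- function(grid, R = 6371) {
  band <- cell_area_km2(grid, R = R)
  matrix(band, nrow = length(grid$lon), ncol = length(grid$lat), byrow = TRUE)
}
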