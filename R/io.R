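#' Write a gridded cube to NetCDF
#'
#' CF-style layout: dimensions `lon`, `lat`, `time`; time stored as days
#' since 1970-01-01; values written as `tas` (degC, daily temperature),
#' `spei` (unitless) or `events` (monthly counts, with a companion `mask`
#' variable and an `event_class` global attribute).
#'
#' @param cube A [temperature_cube()], [spei_cube()] or [event_counts()]
#'   object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  grid <- cube$grid
  dl <- ncdf4::ncdim_def("lon", "degrees_east", grid$lon)
  dla <- ncdf4::ncdim_def("lat", "degrees_north", grid$lat)
  tvals <- as.integer(if (inherits(cube, "temperature_cube")) cube$dates else cube$months)
  dt <- ncdf4::ncdim_def("time", "days since 1970-01-01", tvals)
  if (inherits(cube, "temperature_cube")) {
    v <- ncdf4::ncvar_def("tas", "degC", list(dl, dla, dt), missval = 1e30, prec = "double")
    nc <- ncdf4::nc_create(path, v)
    on.exit(ncdf4::nc_close(nc))
    ncdf4::ncvar_put(nc, v, ifelse(is.na(cube$values), 1e30, cube$values))
  } else if (inherits(cube, "spei_cube")) {
    v <- ncdf4::ncvar_def("spei", "1", list(dl, dla, dt), missval = 1e30, prec = "double")
    nc <- ncdf4::nc_create(path, v)
    on.exit(ncdf4::nc_close(nc))
    ncdf4::ncvar_put(nc, v, ifelse(is.na(cube$values), 1e30, cube$values))
  } else if (inherits(cube, "event_counts")) {
    v <- ncdf4::ncvar_def("events", "count", list(dl, dla, dt), missval = -1L, prec = "integer")
    m <- ncdf4::ncvar_def("mask", "1", list(dl, dla), prec = "integer")
    nc <- ncdf4::nc_create(path, list(v, m))
    on.exit(ncdf4::nc_close(nc))
    ncdf4::ncvar_put(nc, v, cube$counts)
    ncdf4::ncvar_put(nc, m, cube$mask * 1L)
    ncdf4::ncatt_put(nc, 0, "event_class", cube$event_class)
  } else stop("unsupported cube class", call. = FALSE)
  ncdf4::ncatt_put(nc, 0, "dlon", grid$dlon)
  ncdf4::ncatt_put(nc, 0, "dlat", grid$dlat)
  invisible(path)
}

#' Read a gridded cube from NetCDF
#'
#' Recognizes the layouts written by [write_cube()] by variable name.
#'
#' @param path NetCDF file path.
#' @return A [temperature_cube()], [spei_cube()] or [event_counts()].
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  grid <- grid_from_nc(nc)
  tt <- as.Date(as.integer(ncdf4::ncvar_get(nc, "time")), origin = "1970-01-01")
  vars <- names(nc$var)
  arr3 <- function(x, nt) {
    # ncvar_get drops length-1 dimensions; restore them
    array(x, c(length(grid$lon), length(grid$lat), nt))
  }
  if ("tas" %in% vars) {
    v <- arr3(ncdf4::ncvar_get(nc, "tas"), length(tt))
    v[v > 9e29] <- NA
    temperature_cube(grid, tt, v)
  } else if ("spei" %in% vars) {
    v <- arr3(ncdf4::ncvar_get(nc, "spei"), length(tt))
    v[v > 9e29] <- NA
    spei_cube(grid, tt, v)
  } else if ("events" %in% vars) {
    v <- arr3(ncdf4::ncvar_get(nc, "events"), length(tt))
    msk <- matrix(as.integer(ncdf4::ncvar_get(nc, "mask")),
                  length(grid$lon), length(grid$lat)) > 0L
    cls <- ncdf4::ncatt_get(nc, 0, "event_class")$value
    event_counts(grid, tt, v, cls, msk)
  } else stop("unrecognized cube file (no tas/spei/events variable)", call. = FALSE)
}

#' Write a 2-D field to NetCDF
#'
#' Works for [difference_field()] objects, hazard layers (written as 0/1
#' with the threshold rule in global attributes) and bare matrices.
#'
#' @param field The field object.
#' @param path Output path.
#' @param grid Required when `field` is a bare matrix.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path, grid = NULL) {
  if (inherits(field, "difference_field")) {
    vals <- field$values; grid <- field$grid
    attrs <- list(event_class = field$event_class)
  } else if (inherits(field, "hazard_layer")) {
    vals <- field$inside * 1L; grid <- field$grid
    attrs <- list(event_class = field$event_class,
                  threshold_rule = field$threshold_rule$type,
                  threshold_value = field$threshold_value)
  } else {
    stopifnot(is.matrix(field), !is.null(grid))
    vals <- field; attrs <- list()
  }
  dl <- ncdf4::ncdim_def("lon", "degrees_east", grid$lon)
  dla <- ncdf4::ncdim_def("lat", "degrees_north", grid$lat)
  v <- ncdf4::ncvar_def("value", "1", list(dl, dla), missval = 1e30, prec = "double")
  nc <- ncdf4::nc_create(path, v)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, v, ifelse(is.na(vals), 1e30, vals))
  for (nm in names(attrs)) ncdf4::ncatt_put(nc, 0, nm, attrs[[nm]])
  ncdf4::ncatt_put(nc, 0, "dlon", grid$dlon)
  ncdf4::ncatt_put(nc, 0, "dlat", grid$dlat)
  invisible(path)
}

grid_from_nc <- function(nc) {
  a <- ncdf4::ncatt_get(nc, 0)
  grid_spec(as.numeric(ncdf4::ncvar_get(nc, "lon")),
            as.numeric(ncdf4::ncvar_get(nc, "lat")),
            dlon = if (isTRUE(a$dlon > 0)) a$dlon else NULL,
            dlat = if (isTRUE(a$dlat > 0)) a$dlat else NULL)
}

#' Read a 2-D field written by [write_field()]
#'
#' @param path NetCDF path.
#' @return List with `grid`, `values` matrix and any stored attributes.
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  grid <- grid_from_nc(nc)
  v <- matrix(ncdf4::ncvar_get(nc, "value"), length(grid$lon), length(grid$lat))
  v[v > 9e29] <- NA
  atts <- ncdf4::ncatt_get(nc, 0)
  list(grid = grid, values = v, attributes = atts)
}

#' Write species ranges to GeoJSON
#'
#' One MultiPolygon feature per species with `binomial`, `order`, `family`
#' and `genus` properties, in geographic WGS84 coordinates.
#'
#' @param ranges List of [species_range()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranges <- function(ranges, path) {
  features <- lapply(ranges, function(r) {
    coords <- lapply(r$parts, function(p) {
      ring <- rbind(p, p[1, , drop = FALSE])   # close the ring
      dimnames(ring) <- NULL
      list(ring)
    })
    list(type = "Feature",
         properties = list(binomial = r$species_id, order = r$order,
                           family = r$family, genus = r$genus),
         geometry = list(type = "MultiPolygon", coordinates = coords))
  })
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(name = "urn:ogc:def:crs:OGC:1.3:CRS84")),
             features = features)
  json <- jsonlite::toJSON(fc, auto_unbox = TRUE, digits = 10)
  writeLines(json, path)
  invisible(path)
}

#' Read species ranges from GeoJSON
#'
#' Accepts Polygon and MultiPolygon features (outer rings only; holes are
#' rejected). A CRS other than geographic WGS84 / CRS84 is an error:
#' reproject the file to longitude/latitude before reading.
#'
#' @param path GeoJSON file path.
#' @return List of [species_range()] objects.
#' @export
read_ranges <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection", call. = FALSE)
  crs_name <- tryCatch(fc$crs$properties$name, error = function(e) NULL)
  if (!is.null(crs_name) &&
      !grepl("CRS84|4326|WGS\\s*84", crs_name, ignore.case = TRUE))
    stop(sprintf("unsupported CRS '%s': reproject to geographic WGS84 (EPSG:4326) first",
                 crs_name), call. = FALSE)
  ring_mat <- function(ring) do.call(rbind, lapply(ring, function(pt)
    c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
  lapply(fc$features, function(f) {
    g <- f$geometry
    polys <- switch(g$type,
                    Polygon = list(g$coordinates),
                    MultiPolygon = g$coordinates,
                    stop(sprintf("unsupported geometry type '%s'", g$type), call. = FALSE))
    parts <- lapply(polys, function(poly) {
      if (length(poly) > 1L)
        stop("polygons with interior rings (holes) are not supported", call. = FALSE)
      ring_mat(poly[[1]])
    })
    pr <- f$properties
    getp <- function(nm) if (is.null(pr[[nm]])) NA_character_ else as.character(pr[[nm]])
    id <- if (!is.null(pr$binomial)) pr$binomial else pr$species_id
    if (is.null(id)) stop("feature without binomial/species_id property", call. = FALSE)
    species_range(id, parts, order = getp("order"), family = getp("family"),
                  genus = getp("genus"))
  })
}

#' Read / write a CSV table
#'
#' Thin wrappers kept for a uniform I/O surface across the pipeline.
#'
#' @param x Data frame.
#' @param path CSV path.
#' @return The data frame (read) or `path` invisibly (write).
#' @export
write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run manifest
#'
#' Records the configuration snapshot, input-file MD5 digests, package
#' version, seed and stage timings of a pipeline run, so identical inputs
#' are verifiably reproducible.
#'
#' @param config An [analysis_config()].
#' @param inputs Character vector of input file paths.
#' @param seed Integer seed.
#' @param timings Named numeric vector of stage timings (seconds).
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(config, inputs = character(0), seed = NA_integer_,
                         timings = numeric(0)) {
  structure(list(package = "amphex",
                 version = as.character(utils::packageVersion("amphex")),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 seed = seed,
                 config = unclass(config),
                 inputs = if (length(inputs))
                   as.list(tools::md5sum(inputs)) else list(),
                 timings = as.list(timings)),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param dir Output directory (one manifest per output directory).
#' @export
write_manifest <- function(manifest, dir) {
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
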