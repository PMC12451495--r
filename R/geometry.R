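#' Species range as a lon/lat multipolygon
#'
#' A range is one or more simple polygon parts (possibly disjunct
#' populations) in geographic WGS84 coordinates, plus taxonomy labels.
#' Rings are stored open (no repeated closing vertex); consecutive
#' duplicate vertices are removed and degenerate parts (< 3 distinct
#' vertices) rejected. Holes are not supported.
#'
#' @param species_id Character identifier (e.g. a binomial).
#' @param parts A single 2-column matrix `(lon, lat)` or a list of them.
#' @param order,family,genus Optional taxonomy labels.
#' @return An object of class `species_range`.
#' @export
species_range <- function(species_id, parts, order = NA_character_,
                          family = NA_character_, genus = NA_character_) {
  if (is.matrix(parts)) parts <- list(parts)
  parts <- lapply(parts, clean_ring)
  if (!length(parts)) stop("range has no valid polygon part", call. = FALSE)
  structure(list(species_id = as.character(species_id), parts = parts,
                 order = order, family = family, genus = genus),
            class = "species_range")
}

clean_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2L || !is.numeric(ring) || anyNA(ring))
    stop("a polygon part must be a numeric 2-column (lon, lat) matrix", call. = FALSE)
  n <- nrow(ring)
  if (n > 1L && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  dup <- c(FALSE, rowSums(abs(diff(ring))) == 0)
  ring <- ring[!dup, , drop = FALSE]
  if (nrow(ring) < 3L) stop("polygon part has fewer than 3 distinct vertices", call. = FALSE)
  dimnames(ring) <- NULL
  ring
}

#' @export
print.species_range <- function(x, ...) {
  cat(sprintf("<species_range> %s (%s / %s), %d part(s), ~%.0f km2\n",
              x$species_id, x$order, x$family, length(x$parts),
              range_area_km2(x)))
  invisible(x)
}

ring_bbox <- function(ring) {
  c(xmin = min(ring[, 1]), xmax = max(ring[, 1]),
    ymin = min(ring[, 2]), ymax = max(ring[, 2]))
}

bbox_overlap <- function(a, b) {
  a["xmin"] < b["xmax"] && b["xmin"] < a["xmax"] &&
    a["ymin"] < b["ymax"] && b["ymin"] < a["ymax"]
}

#' Spherical polygon area
#'
#' Area of a simple lon/lat polygon on a sphere: edges are straight lines
#' in lon/lat space (densified in latitude) and area is the shoelace sum in
#' `(lon_radians, sin(lat))` coordinates times `R^2`, i.e. the exact
#' integral of the spherical area element under the cylindrical equal-area
#' transform.
#'
#' @param ring 2-column (lon, lat) matrix, open ring.
#' @param R Sphere radius in km.
#' @param max_step Maximum latitude step (degrees) when densifying edges.
#' @return Area in km^2 (non-negative).
#' @keywords internal
ring_area_km2 <- function(ring, R = 6371, max_step = 0.25) {
  dy <- abs(diff(ring[c(seq_len(nrow(ring)), 1L), 2]))
  if (any(dy > max_step)) ring <- densify_ring(ring, max_step)
  x <- ring[, 1] * pi / 180
  y <- sin(ring[, 2] * pi / 180)
  n <- nrow(ring)
  nxt <- c(2:n, 1L)
  abs(sum(x * y[nxt] - x[nxt] * y)) / 2 * R^2
}

densify_ring <- function(ring, max_step) {
  n <- nrow(ring)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    a <- ring[k, ]; b <- ring[if (k == n) 1L else k + 1L, ]
    nseg <- max(1L, ceiling(abs(b[2] - a[2]) / max_step))
    t <- (seq_len(nseg) - 1L) / nseg
    out[[k]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

#' Analytic total area of a range (km^2)
#'
#' Sums spherical part areas; parts are assumed non-overlapping (the
#' synthetic generator guarantees this). Grid-consistent areas used for
#' exposure proportions are computed per cell by [overlap_proportion()]
#' instead.
#'
#' @param range A [species_range()].
#' @return Area in km^2.
#' @export
range_area_km2 <- function(range) {
  sum(vapply(range$parts, ring_area_km2, numeric(1)))
}

# Sutherland-Hodgman clip of an arbitrary simple ring by one half-plane.
# keep(p) must be TRUE on the retained side; cross(a, b) returns the
# boundary intersection of segment a-b.
clip_halfplane <- function(ring, keep, cross) {
  n <- nrow(ring)
  if (n == 0L) return(ring)
  out <- matrix(numeric(0), 0, 2)
  kv <- keep(ring)
  for (k in seq_len(n)) {
    a <- ring[k, ]; b <- ring[if (k == n) 1L else k + 1L, ]
    ka <- kv[k]; kb <- kv[if (k == n) 1L else k + 1L]
    if (ka) out <- rbind(out, a)
    if (xor(ka, kb)) out <- rbind(out, cross(a, b))
  }
  out
}

# Clip a ring to an axis-aligned rectangle b = c(xmin, xmax, ymin, ymax).
clip_ring_rect <- function(ring, b) {
  r <- ring
  r <- clip_halfplane(r, function(p) p[, 1] >= b[1], function(a, q) {
    t <- (b[1] - a[1]) / (q[1] - a[1]); c(b[1], a[2] + t * (q[2] - a[2])) })
  if (nrow(r) < 3L) return(r[0, , drop = FALSE])
  r <- clip_halfplane(r, function(p) p[, 1] <= b[2], function(a, q) {
    t <- (b[2] - a[1]) / (q[1] - a[1]); c(b[2], a[2] + t * (q[2] - a[2])) })
  if (nrow(r) < 3L) return(r[0, , drop = FALSE])
  r <- clip_halfplane(r, function(p) p[, 2] >= b[3], function(a, q) {
    t <- (b[3] - a[2]) / (q[2] - a[2]); c(a[1] + t * (q[1] - a[1]), b[3]) })
  if (nrow(r) < 3L) return(r[0, , drop = FALSE])
  r <- clip_halfplane(r, function(p) p[, 2] <= b[4], function(a, q) {
    t <- (b[4] - a[2]) / (q[2] - a[2]); c(a[1] + t * (q[1] - a[1]), b[4]) })
  if (nrow(r) < 3L) return(r[0, , drop = FALSE])
  r
}

# Clip a ring to a convex polygon (vertices in any consistent orientation).
clip_ring_convex <- function(ring, clip) {
  clip <- clean_ring(clip)
  # force counter-clockwise orientation of the clip ring
  n <- nrow(clip)
  nxt <- c(2:n, 1L)
  if (sum(clip[, 1] * clip[nxt, 2] - clip[nxt, 1] * clip[, 2]) < 0)
    clip <- clip[rev(seq_len(n)), , drop = FALSE]
  r <- ring
  n <- nrow(clip)
  for (k in seq_len(n)) {
    a <- clip[k, ]; b <- clip[if (k == n) 1L else k + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    keep <- function(p) ex * (p[, 2] - a[2]) - ey * (p[, 1] - a[1]) >= 0
    cross <- function(p, q) {
      den <- ex * (q[2] - p[2]) - ey * (q[1] - p[1])
      t <- (ey * (p[1] - a[1]) - ex * (p[2] - a[2])) / den
      c(p[1] + t * (q[1] - p[1]), p[2] + t * (q[2] - p[2]))
    }
    r <- clip_halfplane(r, keep, cross)
    if (nrow(r) < 3L) return(r[0, , drop = FALSE])
  }
  r
}

# Even-odd point-in-ring test (boundary points are implementation-defined).
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  x <- ring[, 1]; y <- ring[, 2]
  xj <- x[c(n, seq_len(n - 1L))]; yj <- y[c(n, seq_len(n - 1L))]
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    crosses <- ((y[k] > py) != (yj[k] > py))
    if (any(crosses)) {
      xint <- x[k] + (py[crosses] - y[k]) / (yj[k] - y[k]) * (xj[k] - x[k])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
  }
  inside
}

point_in_parts <- function(px, py, parts) {
  hit <- rep(FALSE, length(px))
  for (p in parts) {
    todo <- !hit
    if (!any(todo)) break
    hit[todo] <- point_in_ring(px[todo], py[todo], p)
  }
  hit
}

# Per-cell spherical intersection areas of a range with a grid.
# Returns data.frame(i, j, area_km2) for cells with positive overlap.
# Exact Sutherland-Hodgman clipping per part; when clipped pieces of
# several parts overlap inside one cell, the union area there falls back
# to a deterministic 64x64 subcell integration.
range_cell_areas <- function(range, grid, R = 6371) {
  dl2 <- grid$dlon / 2; dp2 <- grid$dlat / 2
  lonmin <- grid$lon - dl2; lonmax <- grid$lon + dl2
  latmin <- grid$lat - dp2; latmax <- grid$lat + dp2
  acc <- new.env(parent = emptyenv())   # key "i_j" -> list of clipped pieces
  for (part in range$parts) {
    bb <- ring_bbox(part)
    is_ <- which(lonmax > bb["xmin"] & lonmin < bb["xmax"])
    js <- which(latmax > bb["ymin"] & latmin < bb["ymax"])
    for (j in js) for (i in is_) {
      piece <- clip_ring_rect(part, c(lonmin[i], lonmax[i], latmin[j], latmax[j]))
      if (nrow(piece) >= 3L && ring_area_km2(piece, R) > 1e-9) {
        key <- paste0(i, "_", j)
        acc[[key]] <- c(acc[[key]], list(piece))
      }
    }
  }
  keys <- ls(acc)
  if (!length(keys))
    return(data.frame(i = integer(0), j = integer(0), area_km2 = numeric(0)))
  ij <- do.call(rbind, strsplit(keys, "_"))
  i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
  area <- numeric(length(keys))
  for (k in seq_along(keys)) {
    pieces <- acc[[keys[k]]]
    if (length(pieces) == 1L) {
      area[k] <- ring_area_km2(pieces[[1]], R)
    } else {
      bbs <- lapply(pieces, ring_bbox)
      overlapping <- FALSE
      for (a in seq_len(length(bbs) - 1L)) for (b in (a + 1L):length(bbs))
        if (bbox_overlap(bbs[[a]], bbs[[b]])) overlapping <- TRUE
      if (!overlapping) {
        area[k] <- sum(vapply(pieces, ring_area_km2, numeric(1), R = R))
      } else {
        area[k] <- union_area_subcells(range$parts, grid, i[k], j[k], R)
      }
    }
  }
  ord <- order(j, i)
  data.frame(i = i[ord], j = j[ord], area_km2 = area[ord])
}

# Union area of range parts within one cell by fixed subcell integration
# (used only when exact clipping cannot resolve overlapping pieces).
union_area_subcells <- function(parts, grid, i, j, R = 6371, nsub = 128L) {
  b <- cell_bounds(grid, i, j)
  xs <- b["xmin"] + (seq_len(nsub) - 0.5) * (b["xmax"] - b["xmin"]) / nsub
  ys <- b["ymin"] + (seq_len(nsub) - 0.5) * (b["ymax"] - b["ymin"]) / nsub
  dlam <- (b["xmax"] - b["xmin"]) / nsub * pi / 180
  ytop <- (b["ymin"] + seq_len(nsub) * (b["ymax"] - b["ymin"]) / nsub) * pi / 180
  ybot <- (b["ymin"] + (seq_len(nsub) - 1L) * (b["ymax"] - b["ymin"]) / nsub) * pi / 180
  wrow <- R^2 * dlam * (sin(ytop) - sin(ybot))
  px <- rep(xs, times = nsub)
  py <- rep(ys, each = nsub)
  hit <- point_in_parts(px, py, parts)
  sum(wrow[rep(seq_len(nsub), each = nsub)][hit])
}
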