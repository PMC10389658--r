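# Planar geometry on polyclip-style polygons.
#
# A polygon ("poly") is a list of rings; each ring is list(x =, y =) with
# vertices in order and no repeated closing vertex.  Positively oriented
# (counter-clockwise) rings are exterior boundaries, negatively oriented rings
# are holes, so the signed shoelace areas of all rings sum to the enclosed
# area.  This is the convention polyclip emits and we preserve it everywhere.

# Authalic Earth radius, km: gives a sphere with the Earth's surface area.
EARTH_RADIUS_KM <- 6371.0088

#' Project lon/lat to world sinusoidal coordinates
#'
#' The world sinusoidal projection is equal-area: `x = R * lon * cos(lat)`,
#' `y = R * lat` (angles in radians).  It is used for every area measurement
#' and for constructing fixed-radius buffers so that buffer area does not
#' depend on latitude.
#'
#' @param lon,lat numeric vectors of WGS84 coordinates in degrees.
#' @return list with numeric `x`, `y` in kilometres.
#' @export
project_sinusoidal <- function(lon, lat) {
  stopifnot(length(lon) == length(lat))
  lam <- lon * pi / 180
  phi <- lat * pi / 180
  list(x = EARTH_RADIUS_KM * lam * cos(phi), y = EARTH_RADIUS_KM * phi)
}

#' Inverse of [project_sinusoidal()]
#'
#' @param x,y sinusoidal coordinates in kilometres.
#' @return list with numeric `lon`, `lat` in degrees.
#' @export
unproject_sinusoidal <- function(x, y) {
  phi <- y / EARTH_RADIUS_KM
  lam <- x / (EARTH_RADIUS_KM * cos(phi))
  list(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

# signed shoelace area of one ring (positive = counter-clockwise)
ring_area <- function(ring) {
  x <- ring$x; y <- ring$y
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

# area of a poly in the units of its coordinates (holes subtract)
poly_area <- function(poly) {
  if (length(poly) == 0L) return(0)
  sum(vapply(poly, ring_area, numeric(1)))
}

#' Area of a lon/lat polygon in square kilometres
#'
#' Vertices are projected to the world sinusoidal (equal-area) projection and
#' the shoelace formula applied ring by ring; holes subtract.
#'
#' @param poly a polygon: list of rings, each `list(x =, y =)` in degrees.
#' @return area in km^2.
#' @export
poly_area_km2 <- function(poly) {
  if (length(poly) == 0L) return(0)
  sum(vapply(poly, function(r) {
    p <- project_sinusoidal(r$x, r$y)
    ring_area(list(x = p$x, y = p$y))
  }, numeric(1)))
}

poly_bbox <- function(poly) {
  xs <- unlist(lapply(poly, `[[`, "x"))
  ys <- unlist(lapply(poly, `[[`, "y"))
  c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

poly_is_empty <- function(poly) {
  length(poly) == 0L || abs(poly_area(poly)) < .Machine$double.eps
}

poly_intersect <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(list())
  polyclip::polyclip(a, b, op = "intersection")
}

poly_union2 <- function(a, b) {
  if (length(a) == 0L) return(b)
  if (length(b) == 0L) return(a)
  polyclip::polyclip(a, b, op = "union")
}

# union of a list of polys; divide-and-conquer keeps intermediate results small
poly_union_all <- function(polys) {
  polys <- polys[lengths(polys) > 0L]
  if (length(polys) == 0L) return(list())
  while (length(polys) > 1L) {
    out <- vector("list", ceiling(length(polys) / 2))
    for (k in seq_along(out)) {
      i <- 2L * k - 1L
      out[[k]] <- if (i + 1L <= length(polys)) {
        poly_union2(polys[[i]], polys[[i + 1L]])
      } else {
        polys[[i]]
      }
    }
    polys <- out
  }
  polys[[1L]]
}

rect_poly <- function(xmin, xmax, ymin, ymax) {
  list(list(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax)))
}

#' Test points against a polygon (even-odd rule, strict interior)
#'
#' Rings are combined with the even-odd rule, so holes are handled without
#' regard to orientation.  Points exactly on a ring edge or vertex are
#' classified as outside (strict interior), matching the cell-inclusion rule
#' used by the zonal statistics.
#'
#' @param px,py numeric point coordinates.
#' @param poly polygon as a list of rings.
#' @return logical vector, `TRUE` for points strictly inside.
#' @export
points_in_polygon <- function(px, py, poly) {
  inside <- rep(FALSE, length(px))
  if (length(poly) == 0L || length(px) == 0L) return(inside)
  for (ring in poly) {
    code <- sp::point.in.polygon(px, py, ring$x, ring$y)
    inside <- xor(inside, code == 1L)
    inside[code >= 2L] <- FALSE   # boundary: strictly-inside rule
  }
  inside
}

# ---- GeoJSON ---------------------------------------------------------------

# group rings of a poly into GeoJSON MultiPolygon nesting:
# each positive ring becomes an outer boundary; each negative ring is attached
# as a hole of the outer ring that contains its first vertex.
poly_to_multipolygon_coords <- function(poly) {
  areas <- vapply(poly, ring_area, numeric(1))
  outers <- which(areas >= 0)
  holes <- which(areas < 0)
  close_ring <- function(r) {
    xs <- c(r$x, r$x[1]); ys <- c(r$y, r$y[1])
    lapply(seq_along(xs), function(i) c(xs[i], ys[i]))
  }
  parts <- lapply(outers, function(i) list(close_ring(poly[[i]])))
  for (h in holes) {
    hit <- which(vapply(outers, function(i) {
      points_in_polygon(poly[[h]]$x[1], poly[[h]]$y[1], poly[i])
    }, logical(1)))[1]
    if (is.na(hit)) hit <- 1L
    parts[[hit]] <- c(parts[[hit]], list(close_ring(poly[[h]])))
  }
  parts
}

multipolygon_coords_to_poly <- function(coords) {
  rings <- list()
  for (part in coords) {
    for (ring in part) {
      m <- do.call(rbind, lapply(ring, function(p) as.numeric(p[1:2])))
      n <- nrow(m)
      if (n > 1 && m[1, 1] == m[n, 1] && m[1, 2] == m[n, 2]) m <- m[-n, , drop = FALSE]
      rings <- c(rings, list(list(x = m[, 1], y = m[, 2])))
    }
  }
  rings
}

#' Write polygons to a GeoJSON FeatureCollection
#'
#' @param polys named list of polygons (lon/lat degrees).
#' @param path output file.
#' @param properties optional data frame of per-feature properties, one row
#'   per polygon, aligned with `polys`.
#' @export
write_polygons_geojson <- function(polys, path, properties = NULL) {
  feats <- lapply(seq_along(polys), function(i) {
    props <- if (is.null(properties)) {
      list(id = names(polys)[i])
    } else {
      c(list(id = names(polys)[i]), as.list(properties[i, , drop = FALSE]))
    }
    list(
      type = "Feature",
      properties = props,
      geometry = list(
        type = "MultiPolygon",
        coordinates = poly_to_multipolygon_coords(polys[[i]])
      )
    )
  }
  )
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from a GeoJSON FeatureCollection
#'
#' Accepts Polygon and MultiPolygon features; feature `id` property (or
#' sequential index) names the result.
#'
#' @param path GeoJSON file.
#' @return named list of polygons.
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection")
  }
  out <- list()
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    geom <- f$geometry
    coords <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type)
    )
    id <- f$properties$id
    if (is.null(id)) id <- as.character(i)
    out[[id]] <- multipolygon_coords_to_poly(coords)
  }
  out
}
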