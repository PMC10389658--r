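# Constrained Voronoi sampling regions.
#
# Each language's environmental catchment is built in four steps: a 100 km
# buffer constructed in the world sinusoidal equal-area projection, clipped
# to the coastline, a planar Voronoi partition of the bounding box in
# unprojected lon/lat, and finally the intersection of each language's
# Voronoi cell with the *combined* land-clipped buffers of all languages.
# The last step deliberately uses the combined buffer union rather than the
# language's own buffer: this mirrors the source GIS workflow and produces
# the documented "inflation" artifact in which a few regions exceed their
# own buffer area.

#' Build fixed-radius equal-area buffers around points
#'
#' Each buffer is a regular polygon (default 128 segments) of the given
#' radius constructed around the projected point in the world sinusoidal
#' projection, then transformed back to lon/lat, so its area is latitude
#' independent.
#'
#' @param points data frame with `id`, `lon`, `lat` (degrees, unique ids).
#' @param radius_km buffer radius in kilometres (> 0; default 100).
#' @param n_segments vertices of the polygonal circle approximation.
#' @return named list of polygons (lon/lat), one per point.
#' @export
build_buffers <- function(points, radius_km = 100, n_segments = 128) {
  stopifnot(is.data.frame(points), all(c("id", "lon", "lat") %in% names(points)))
  if (!is.numeric(radius_km) || radius_km <= 0) {
    stop("radius_km must be > 0", call. = FALSE)
  }
  if (anyDuplicated(points$id)) stop("point ids must be unique", call. = FALSE)
  if (any(abs(points$lat) > 89)) {
    stop("points within 1 degree of a pole cannot be buffered", call. = FALSE)
  }
  theta <- 2 * pi * (seq_len(n_segments) - 1) / n_segments
  out <- vector("list", nrow(points))
  names(out) <- points$id
  for (i in seq_len(nrow(points))) {
    c_xy <- project_sinusoidal(points$lon[i], points$lat[i])
    ll <- unproject_sinusoidal(c_xy$x + radius_km * cos(theta),
                               c_xy$y + radius_km * sin(theta))
    if (any(!is.finite(ll$lon)) || any(abs(ll$lat) > 90)) {
      stop("buffer produces invalid geometry for point ", points$id[i],
           call. = FALSE)
    }
    out[[i]] <- list(list(x = ll$lon, y = ll$lat))
  }
  out
}

#' Clip buffers to the coastline
#'
#' Intersects each buffer with the land multipolygon, excluding off-shore
#' area.  Buffers left empty (point off all land) are kept as empty polygons
#' and reported with a warning.
#'
#' @param buffers named list of polygons from [build_buffers()].
#' @param coastline land multipolygon (lon/lat).
#' @return named list of clipped polygons.
#' @export
clip_to_land <- function(buffers, coastline) {
  if (length(coastline) == 0L) stop("empty coastline geometry", call. = FALSE)
  out <- lapply(buffers, function(b) poly_intersect(b, coastline))
  empty <- names(out)[vapply(out, poly_is_empty, logical(1))]
  if (length(empty) > 0) {
    warning("buffer entirely off land for: ", paste(empty, collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Planar Voronoi cells in lon/lat coordinates
#'
#' Voronoi adjacency is computed planar in unprojected degrees over a
#' rectangular bounding box (the projection distortion this implies is a
#' deliberate property of the workflow being reproduced; areas are always
#' measured in the equal-area projection).  Coincident points are rejected.
#'
#' @param points data frame with `id`, `lon`, `lat`.
#' @param bounding_box numeric `c(xmin, xmax, ymin, ymax)`; default the
#'   whole world `[-180, 180] x [-90, 90]`.
#' @return named list of convex cell polygons tiling the box.
#' @export
build_voronoi <- function(points, bounding_box = c(-180, 180, -90, 90)) {
  stopifnot(nrow(points) >= 1)
  if (any(points$lon < bounding_box[1] | points$lon > bounding_box[2] |
            points$lat < bounding_box[3] | points$lat > bounding_box[4])) {
    stop("bounding box must contain all points", call. = FALSE)
  }
  if (any(abs(points$lon) > 178)) {
    warning("points within 2 degrees of the antimeridian: planar cells do not wrap",
            call. = FALSE)
  }
  dmat <- as.matrix(stats::dist(points[, c("lon", "lat")]))
  diag(dmat) <- Inf
  if (nrow(points) > 1 && min(dmat) < 1e-6) {
    stop("coincident points (separation < 1e-6 degrees) are not allowed",
         call. = FALSE)
  }
  if (nrow(points) == 1L) {
    cell <- rect_poly(bounding_box[1], bounding_box[2],
                      bounding_box[3], bounding_box[4])
    return(stats::setNames(list(cell), points$id))
  }
  dd <- deldir::deldir(points$lon, points$lat, rw = bounding_box,
                       suppressMsge = TRUE)
  tiles <- deldir::tile.list(dd)
  out <- vector("list", nrow(points))
  names(out) <- points$id
  for (t in tiles) {
    out[[t$ptNum]] <- list(list(x = t$x, y = t$y))
  }
  out
}

#' Constrain Voronoi cells by the combined clipped buffers
#'
#' Each sampling region is `cell_i` intersected with the union of *all*
#' land-clipped buffers.  Areas (km^2) are measured in the sinusoidal
#' equal-area projection; the inflation ratio is the region area over the
#' language's own clipped-buffer area.
#'
#' @param cells named list from [build_voronoi()].
#' @param clipped_buffers named list from [clip_to_land()] (same names).
#' @param base_buffer_areas optional named numeric of unclipped buffer areas
#'   (km^2), carried into the output for diagnostics.
#' @return tibble with `language_id`, `polygon` (list column),
#'   `base_buffer_area`, `clipped_buffer_area`, `region_area`,
#'   `inflation_ratio`.
#' @export
constrain_cells <- function(cells, clipped_buffers, base_buffer_areas = NULL) {
  stopifnot(setequal(names(cells), names(clipped_buffers)))
  ids <- names(cells)
  buffer_union <- poly_union_all(clipped_buffers)
  if (poly_is_empty(buffer_union)) stop("empty buffer union", call. = FALSE)
  polys <- lapply(ids, function(id) poly_intersect(cells[[id]], buffer_union))
  clipped_area <- unname(vapply(clipped_buffers[ids], poly_area_km2, numeric(1)))
  region_area <- vapply(polys, poly_area_km2, numeric(1))
  tibble::tibble(
    language_id = ids,
    polygon = polys,
    base_buffer_area = if (is.null(base_buffer_areas)) NA_real_
                       else unname(base_buffer_areas[ids]),
    clipped_buffer_area = clipped_area,
    region_area = region_area,
    inflation_ratio = ifelse(clipped_area > 0, region_area / clipped_area, NA_real_)
  )
}

#' Build the full set of sampling regions
#'
#' Convenience wrapper running buffers, coastline clip, Voronoi partition and
#' cell constraint in sequence.
#'
#' @inheritParams build_buffers
#' @inheritParams build_voronoi
#' @param coastline land multipolygon (lon/lat).
#' @return region tibble from [constrain_cells()].
#' @export
build_sampling_regions <- function(points, coastline, radius_km = 100,
                                   bounding_box = c(-180, 180, -90, 90),
                                   n_segments = 128) {
  buffers <- build_buffers(points, radius_km = radius_km, n_segments = n_segments)
  clipped <- clip_to_land(buffers, coastline)
  cells <- build_voronoi(points, bounding_box = bounding_box)
  base_areas <- vapply(buffers, poly_area_km2, numeric(1))
  constrain_cells(cells, clipped, base_buffer_areas = base_areas)
}

#' Report region-area inflation diagnostics
#'
#' Lists every language's inflation ratio (region area over its own clipped
#' buffer area), sorted descending, plus the count and fraction of languages
#' whose sampling region exceeds their own buffer.
#'
#' @param regions region tibble from [constrain_cells()].
#' @param tol ratios above `1 + tol` count as inflated.
#' @return list with `table` (tibble `language_id`, `inflation_ratio`),
#'   `n_inflated`, `fraction_inflated`.
#' @export
inflation_report <- function(regions, tol = 1e-3) {
  tab <- tibble::tibble(language_id = regions$language_id,
                        inflation_ratio = regions$inflation_ratio)
  tab <- tab[order(-tab$inflation_ratio), ]
  flagged <- !is.na(tab$inflation_ratio) & tab$inflation_ratio > 1 + tol
  list(table = tab,
       n_inflated = sum(flagged),
       fraction_inflated = sum(flagged) / nrow(tab))
}

#' Write sampling regions to GeoJSON
#'
#' @param regions region tibble from [constrain_cells()].
#' @param path output GeoJSON file.
#' @export
write_regions_geojson <- function(regions, path) {
  polys <- stats::setNames(regions$polygon, regions$language_id)
  props <- as.data.frame(regions[c("base_buffer_area", "clipped_buffer_area",
                                   "region_area", "inflation_ratio")])
  write_polygons_geojson(polys, path, properties = props)
}

#' Read sampling regions from GeoJSON
#'
#' @param path GeoJSON written by [write_regions_geojson()].
#' @return region tibble (areas recomputed from the geometry if absent).
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  rows <- lapply(feats, function(f) {
    poly <- multipolygon_coords_to_poly(
      if (identical(f$geometry$type, "Polygon")) list(f$geometry$coordinates)
      else f$geometry$coordinates)
    pr <- f$properties
    num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
    tibble::tibble(
      language_id = as.character(pr$id),
      polygon = list(poly),
      base_buffer_area = num(pr$base_buffer_area),
      clipped_buffer_area = num(pr$clipped_buffer_area),
      region_area = num(pr$region_area),
      inflation_ratio = num(pr$inflation_ratio)
    )
  })
  do.call(rbind, rows)
}
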