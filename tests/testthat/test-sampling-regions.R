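# Equal-area buffering, coastline clipping, planar Voronoi partition and the
# constrained sampling regions with their inflation diagnostics.

CIRCLE_100KM <- pi * 100^2   # 31,415.93 km2

test_that("100 km buffers are equal-area across latitudes", {
  pts <- data.frame(id = c("eq", "mid", "high"),
                    lon = c(0, 30, 10), lat = c(0, 40, 70))
  areas <- vapply(build_buffers(pts, radius_km = 100), poly_area_km2, numeric(1))
  expect_true(all(abs(areas - CIRCLE_100KM) / CIRCLE_100KM < 0.01))
  # latitude independence within the polygonal tolerance
  expect_lt(diff(range(areas)) / CIRCLE_100KM, 0.01)
  expect_error(build_buffers(pts, radius_km = 0), "radius")
  expect_error(build_buffers(data.frame(id = "p", lon = 0, lat = 89.9)), "pole")
})

test_that("coastline clipping keeps the on-land part of each buffer", {
  pts <- data.frame(id = c("inland", "coastal", "island"),
                    lon = c(5, 0, -10), lat = c(5, 0, 0))
  bufs <- build_buffers(pts)
  # half-plane land: everything east of lon 0, plus a ~500 km2 island at -10
  land <- list(list(x = c(0, 30, 30, 0), y = c(-20, -20, 20, 20)),
               list(x = c(-10.1, -9.9, -9.9, -10.1),
                    y = c(-0.1, -0.1, 0.1, 0.1)))
  clipped <- clip_to_land(bufs, land)
  a_full <- poly_area_km2(bufs$inland)
  expect_equal(poly_area_km2(clipped$inland), a_full, tolerance = 1e-6)
  # straight coastline through the centre: half the buffer survives
  expect_equal(poly_area_km2(clipped$coastal), a_full / 2,
               tolerance = 0.02)
  # island smaller than the buffer: clipped area = island area
  island_area <- poly_area_km2(list(list(x = c(-10.1, -9.9, -9.9, -10.1),
                                         y = c(-0.1, -0.1, 0.1, 0.1))))
  expect_equal(poly_area_km2(clipped$island), island_area, tolerance = 1e-6)
  # off-land buffer is flagged
  far <- build_buffers(data.frame(id = "sea", lon = -30, lat = 0))
  expect_warning(clip_to_land(far, land), "off land")
})

test_that("planar Voronoi cells tile the box and contain their seeds", {
  box <- c(-10, 10, -10, 10)
  # single point owns the whole box
  one <- build_voronoi(data.frame(id = "a", lon = 0, lat = 0), box)
  expect_equal(abs(voroling:::poly_area(one$a)), 400, tolerance = 1e-9)
  # mirror-symmetric pair splits the box down the bisector
  two <- build_voronoi(data.frame(id = c("l", "r"), lon = c(-3, 3), lat = c(0, 0)),
                       box)
  expect_equal(abs(voroling:::poly_area(two$l)), abs(voroling:::poly_area(two$r)),
               tolerance = 1e-9)
  expect_equal(abs(voroling:::poly_area(two$l)), 200, tolerance = 1e-9)
  # 10 random points: assignment agrees with nearest-seed classification
  set.seed(31)
  pts <- data.frame(id = sprintf("p%02d", 1:10),
                    lon = runif(10, -9, 9), lat = runif(10, -9, 9))
  cells <- build_voronoi(pts, box)
  g <- seq(-10 + 0.02, 10 - 0.02, length.out = 500)
  gx <- rep(g, times = 500); gy <- rep(g, each = 500)
  d2 <- outer(gx, pts$lon, "-")^2 + outer(gy, pts$lat, "-")^2
  nearest <- max.col(-d2)
  assigned <- integer(length(gx))
  for (i in seq_len(nrow(pts))) {
    inside <- points_in_polygon(gx, gy, cells[[pts$id[i]]])
    assigned[inside] <- i
  }
  agree <- mean(assigned == nearest)
  expect_gte(agree, 0.999)
  # coincident points are rejected, empty input too
  expect_error(build_voronoi(data.frame(id = c("a", "b"), lon = c(0, 0),
                                        lat = c(0, 0)), box), "coincident")
})

test_that("constrained regions reproduce the combined-buffer inflation artifact", {
  # land: a broad plane so clipping is a no-op
  land <- list(list(x = c(-5, 10, 10, -5), y = c(-5, -5, 5, 5)))
  box <- c(-5, 10, -5, 5)

  # isolated point: region = own buffer, no inflation
  iso_pts <- data.frame(id = "solo", lon = 2, lat = 0)
  iso <- build_sampling_regions(iso_pts, land, bounding_box = box)
  expect_equal(iso$inflation_ratio, 1, tolerance = 1e-3)
  expect_equal(iso$region_area, iso$clipped_buffer_area, tolerance = 1e-3)

  # two equatorial points 150 km apart: the bisector trims each buffer and,
  # because a point nearest seed i that lies in any equal-radius buffer is
  # necessarily within the radius of i, neither region can exceed its own
  # buffer here -- both ratios sit below 1
  sep_deg <- 150 / 111.19495  # 150 km along the equator, in degrees
  pts <- data.frame(id = c("w", "e"), lon = c(0, sep_deg), lat = c(0, 0))
  regs <- build_sampling_regions(pts, land, bounding_box = box)
  expect_true(all(regs$inflation_ratio < 1))
  expect_equal(inflation_report(regs)$n_inflated, 0)

  # grid membership oracle for the two-point areas: nearest seed within the
  # union of the two buffers, cell areas integrated on the sphere
  g <- 1000
  gx <- seq(-1.2, sep_deg + 1.2, length.out = g)
  gy <- seq(-1.2, 1.2, length.out = g)
  px <- rep(gx, times = g); py <- rep(gy, each = g)
  bufs <- build_buffers(pts)
  in_u <- points_in_polygon(px, py, bufs$w) | points_in_polygon(px, py, bufs$e)
  d_w <- (px - 0)^2 + (py - 0)^2
  d_e <- (px - sep_deg)^2 + (py - 0)^2
  deg_km <- pi / 180 * 6371.0088
  wgt <- (diff(gx)[1] * deg_km * cos(py * pi / 180)) * (diff(gy)[1] * deg_km)
  a_w <- sum(wgt[in_u & d_w < d_e])
  a_e <- sum(wgt[in_u & d_e < d_w])
  expect_equal(regs$region_area[regs$language_id == "w"], a_w, tolerance = 0.01)
  expect_equal(regs$region_area[regs$language_id == "e"], a_e, tolerance = 0.01)
})

test_that("coastline clipping at high latitude can inflate a region past its own buffer", {
  # the inflation artifact needs the degree-metric Voronoi partition to
  # disagree with the km-metric buffers, amplified by coastline clipping:
  # a neighbour's land-clipped buffer then contributes area inside this
  # language's cell but beyond its own (clipped) buffer
  set.seed(39)
  n <- sample(4:8, 1)
  lat0 <- runif(1, 45, 70)
  pts <- data.frame(id = sprintf("p%d", 1:n),
                    lon = runif(n, 0, 6), lat = lat0 + runif(n, -3, 3))
  land <- polyclip::polyclip(
    list(list(x = c(-2, 8, 8, -2), y = lat0 + c(-4, -4, 0.5, 0.5))),
    list(list(x = c(-2, 8, 8, -2), y = lat0 + c(1.0, 1.0, 4, 4))),
    op = "union")
  regs <- suppressWarnings(
    build_sampling_regions(pts, land,
                           bounding_box = c(-2, 8, lat0 - 4, lat0 + 4)))
  rep_out <- inflation_report(regs)
  expect_gte(rep_out$n_inflated, 1)
  expect_equal(rep_out$fraction_inflated, rep_out$n_inflated / nrow(regs))
  # the report is sorted by ratio, descending
  expect_false(is.unsorted(rev(rep_out$table$inflation_ratio), na.rm = TRUE))
})

test_that("regions partition the clipped-buffer union and shrink with radius", {
  w <- cached_world(seed = 42, n_languages = 30L)
  regs <- build_sampling_regions(w$languages, w$land,
                                 bounding_box = w$config$extent)
  bufs <- clip_to_land(build_buffers(w$languages), w$land)
  union_area <- poly_area_km2(voroling:::poly_union_all(bufs))
  expect_equal(sum(regs$region_area), union_area, tolerance = 0.005)
  # interior-disjoint: pairwise overlaps are numerically negligible
  ids <- regs$language_id[1:8]
  for (i in 1:7) {
    for (j in (i + 1):8) {
      ov <- voroling:::poly_intersect(regs$polygon[[i]], regs$polygon[[j]])
      expect_lt(abs(poly_area_km2(ov)), 1e-6 * union_area)
    }
  }
  # monotonicity: shrinking the radius never grows any region
  regs50 <- build_sampling_regions(w$languages, w$land, radius_km = 50,
                                   bounding_box = w$config$extent)
  expect_true(all(regs50$region_area <= regs$region_area + 1e-6))
})

test_that("regions survive a GeoJSON round trip", {
  w <- cached_world(seed = 42, n_languages = 30L)
  regs <- build_sampling_regions(w$languages[1:5, ], w$land,
                                 bounding_box = w$config$extent)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_regions_geojson(regs, path)
  back <- read_regions_geojson(path)
  expect_identical(back$language_id, regs$language_id)
  expect_equal(back$region_area, regs$region_area, tolerance = 1e-9)
  for (i in seq_len(nrow(regs))) {
    expect_equal(poly_area_km2(back$polygon[[i]]),
                 poly_area_km2(regs$polygon[[i]]), tolerance = 1e-9)
  }
})
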