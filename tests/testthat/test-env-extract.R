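# Station summaries, zonal statistics, the naming grammar and the master
# table.

square_region <- function(x0, x1, y0, y1) {
  list(list(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1)))
}

test_that("station records are filtered to an inclusive year window", {
  rec <- tibble::tibble(station_id = "s", lon = 0, lat = 0,
                        year = c(1950L, 1951L, 1965L, 1980L, 1981L),
                        tmin = 1, tmax = 2, tavg = 3, prcp = 4)
  kept <- filter_station_years(rec, c(1951, 1980))
  expect_identical(kept$year, c(1951L, 1965L, 1980L))
  expect_equal(nrow(filter_station_years(rec[0, ], c(1951, 1980))), 0)
  # widening the window never loses records
  wider <- filter_station_years(rec, c(1940, 1990))
  expect_gte(nrow(wider), nrow(kept))
})

test_that("station summaries pool annual values into a grand mean", {
  region <- square_region(0, 1, 0, 1)
  rec <- tibble::tibble(
    station_id = c("a", "a", "a", "out"),
    lon = c(0.5, 0.5, 0.5, 5), lat = c(0.5, 0.5, 0.5, 5),
    year = c(1951L, 1952L, 1953L, 1951L),
    tmin = NA_real_, tmax = NA_real_,
    tavg = c(10, 20, 30, 99), prcp = NA_real_)
  s <- summarize_stations(region, rec)
  expect_equal(s$tavg$mean, 20)
  expect_equal(s$tavg$n, 3L)
  expect_equal(s$tmin$n, 0L)
  expect_true(is.na(s$tmin$mean))
  # empty catchment
  s0 <- summarize_stations(square_region(50, 51, 50, 51), rec)
  expect_true(all(vapply(s0, function(p) p$n == 0L, logical(1))))
  # grand mean over station-years, not a mean of per-station means:
  # station A has 5 years at 0, station B 1 year at 12 -> grand mean 2
  rec2 <- tibble::tibble(
    station_id = c(rep("A", 5), "B"),
    lon = c(rep(0.3, 5), 0.7), lat = 0.5, year = c(1951:1955, 1951L),
    tmin = NA_real_, tmax = NA_real_, tavg = c(rep(0, 5), 12),
    prcp = NA_real_)
  s2 <- summarize_stations(region, rec2)
  expect_equal(s2$tavg$mean, 2)
  expect_equal(s2$tavg$n, 6L)
  # disjoint regions never double-count a station-year
  left <- square_region(0, 0.5, 0, 1)
  right <- square_region(0.5, 1, 0, 1)
  n_split <- summarize_stations(left, rec2)$tavg$n +
    summarize_stations(right, rec2)$tavg$n
  expect_equal(n_split, s2$tavg$n)
})

test_that("zonal statistics match hand-computed values on small rasters", {
  # constant field
  r_const <- env_raster(matrix(5, 4, 4), xmin = 0, ymin = 0, cell_deg = 1)
  z <- zonal_numeric(square_region(0, 4, 0, 4), r_const)
  expect_equal(z$n, 16L)
  expect_equal(z$average, 5)
  expect_equal(z$median, 5)
  expect_equal(z$std_dev, 0)
  expect_equal(z$range, 0)

  # 2x2 with values 1..4: average 2.5, sample variance 5/3, range 3,
  # interpolated quartiles 1.75 / 3.25
  r4 <- env_raster(matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE),
                   xmin = 0, ymin = 0, cell_deg = 1)
  z4 <- zonal_numeric(square_region(0, 2, 0, 2), r4)
  expect_equal(z4$n, 4L)
  expect_equal(z4$average, 2.5)
  expect_equal(z4$median, 2.5)
  expect_equal(z4$variance, 5 / 3, tolerance = 1e-12)
  expect_equal(z4$range, 3)
  expect_equal(z4$first_quartile, 1.75)
  expect_equal(z4$third_quartile, 3.25)
  expect_equal(z4$coeff_var, sqrt(5 / 3) / 2.5, tolerance = 1e-12)

  # nodata cells are counted and excluded
  m <- matrix(1, 3, 3); m[1, 1] <- NA; m[2, 2] <- NA; m[3, 3] <- NA
  rna <- env_raster(m, xmin = 0, ymin = 0, cell_deg = 1)
  zna <- zonal_numeric(square_region(0, 3, 0, 3), rna)
  expect_equal(zna$null_cells, 3L)
  expect_equal(zna$n, 6L)
  expect_equal(zna$average, 1)

  # no contributing cells
  z0 <- zonal_numeric(square_region(10, 11, 10, 11), r4)
  expect_equal(z0$n, 0L)
  expect_true(is.na(z0$average))
})

test_that("zonal statistics agree with a brute-force per-cell oracle", {
  set.seed(77)
  for (k in 1:25) {
    m <- matrix(rnorm(50 * 50), 50, 50)
    m[sample(2500, 60)] <- NA
    r <- env_raster(m, xmin = 0, ymin = 0, cell_deg = 0.2)
    region <- random_region(c(0, 10), c(0, 10))
    z <- zonal_numeric(region, r)
    o <- oracle_zonal(region, r)
    expect_identical(z$n, o$n)
    expect_identical(z$null_cells, o$null_cells)
    if (o$n > 0) {
      for (s in c("minimum", "maximum", "range", "average", "median",
                  "first_quartile", "third_quartile", "std_dev",
                  "variance", "coeff_var")) {
        expect_equal(z[[s]], o[[s]], tolerance = 1e-9, label = s)
      }
    }
  }
})

test_that("categorical zonal counts conserve the cell total", {
  cm <- c(tall = 1, med = 2, short = 3, water = 4, snow = 5)
  # all-water region
  rw <- env_raster(matrix(4L, 5, 2), xmin = 0, ymin = 0, cell_deg = 1,
                   kind = "categorical")
  cw <- zonal_categorical(square_region(0, 2, 0, 5), rw, cm)
  expect_equal(unname(cw["water"]), 10L)
  expect_true(all(cw[setdiff(names(cm), "water")] == 0))
  # mixed split: counts partition the total
  mm <- matrix(c(rep(1L, 6), rep(3L, 4)), 2, 5)
  rm_ <- env_raster(mm, xmin = 0, ymin = 0, cell_deg = 1, kind = "categorical")
  cmix <- zonal_categorical(square_region(0, 5, 0, 2), rm_, cm)
  expect_equal(unname(cmix["tall"]) + unname(cmix["short"]), 10L)
  z <- zonal_numeric(square_region(0, 5, 0, 2),
                     env_raster(mm + 0.0, xmin = 0, ymin = 0, cell_deg = 1))
  expect_equal(sum(cmix), z$n - z$null_cells)
  # region off the raster warns and returns zeros
  expect_warning(c0 <- zonal_categorical(square_region(90, 91, 0, 1), rw, cm),
                 "no raster cells")
  expect_true(all(c0 == 0))
  # unmapped codes are flagged
  expect_warning(zonal_categorical(square_region(0, 2, 0, 5), rw, c(tall = 1)),
                 "missing from class_map")
})

test_that("variable names follow the v_<name>_<units>__<stat> grammar", {
  expect_identical(name_variable("tavg", "dC", "avg"), "v_tavg_dC__avg")
  expect_identical(name_variable("elev", "m", "median"), "v_elev_m__median")
  expect_identical(name_variable("lc_tall", "ct", "sum"), "v_lc_tall_ct__sum")
  expect_identical(name_variable("elev", "m", "std_dev"), "v_elev_m__std_dev")
  expect_error(name_variable("tavg", "d_C", "avg"), "units")
  expect_error(name_variable("tavg", "", "avg"), "units")
  expect_error(name_variable("t__avg", "dC", "avg"), "__")
})

test_that("the master table keeps one row per language with stable columns", {
  w <- cached_world(seed = 42, n_languages = 30L)
  regs <- build_sampling_regions(w$languages, w$land,
                                 bounding_box = w$config$extent)
  env <- extract_environment(regs, w$stations, w$rasters)
  master <- assemble_master_table(w$language_table, regs, env)
  expect_equal(nrow(master), nrow(w$language_table))
  expect_identical(master$id, w$language_table$id)
  expect_true(all(c("region_area_km2", "inflation_ratio",
                    "v_tavg_dC__avg", "v_elev_m__median",
                    "v_lc_water_ct__sum") %in% names(master)))
  # a language without a region keeps its row, env cells empty
  expect_warning(
    m2 <- assemble_master_table(w$language_table, regs[-1, ], env[-1, ]),
    "without a sampling region")
  expect_equal(nrow(m2), nrow(w$language_table))
  expect_true(is.na(m2$region_area_km2[m2$id == w$language_table$id[1]]))
  # round trip preserves numeric content
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(master, path, row.names = FALSE, na = "")
  back <- read.csv(path, check.names = FALSE)
  expect_equal(back$v_tavg_dC__avg, master$v_tavg_dC__avg, tolerance = 1e-9)
  expect_equal(back$v_elev_m__variance, master$v_elev_m__variance,
               tolerance = 1e-9)
})

test_that("ascii grids round-trip including nodata cells", {
  m <- matrix(rnorm(30), 5, 6)
  m[2, 3] <- NA
  r <- env_raster(m, xmin = -3, ymin = 10, cell_deg = 0.25)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, path)
  back <- read_ascii_grid(path)
  expect_equal(back$values, r$values, tolerance = 1e-7)
  expect_equal(back$xmin, r$xmin)
  expect_equal(back$cell_deg, r$cell_deg)
  expect_true(is.na(back$values[2, 3]))
})
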