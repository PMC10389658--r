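# Seeded generator of a miniature world: land/sea polygons, language points
# densest near the equator, spatially autocorrelated environmental rasters
# with realistic inter-correlations, a station network with configurable
# hemispheric coverage bias, phoneme inventories with a planted linear
# dependence of consonant heaviness on local temperature, and a random
# genealogy on the 1-10 relatedness scale.  Every stage derives its own
# sub-seed from the root seed so stages can be regenerated independently
# and a fixed configuration yields a byte-identical world.

#' Configuration for the synthetic world
#'
#' Defaults describe the study conditions the pipeline is validated under: a
#' miniature low-latitude world (80 x 60 degree extent) with about a third
#' land, languages denser near the equator, a standard-atmosphere lapse rate
#' (6.5 degC per km), an equator-to-pole style latitudinal gradient
#' (0.6 degC per degree), a planted consonant-heaviness slope of -0.15 index
#' units per degC with residual noise of 1.0 index units, and the 1951-1980
#' station window.
#'
#' @param seed integer root seed.
#' @param extent `c(lon_min, lon_max, lat_min, lat_max)` in degrees.
#' @param land_fraction_target target land fraction of the extent, in (0, 1).
#' @param n_languages number of language points.
#' @param tropics_bias latitudinal density decay: density is proportional to
#'   `exp(-tropics_bias * |lat| / 90)`; 0 = uniform.
#' @param min_separation_deg minimum separation between language points.
#' @param raster_cell_deg raster cell size, degrees.
#' @param field_smoothness Gaussian correlation length of the random fields,
#'   degrees.
#' @param base_temp sea-level equatorial mean temperature, degC.
#' @param lat_gradient temperature decrease per degree of |latitude|, degC.
#' @param lapse_per_km temperature decrease per km of elevation, degC.
#' @param noise_sd smooth temperature noise, degC.
#' @param effect_intercept,effect_slope,effect_noise_sd planted model:
#'   latent consonant heaviness `h = a + b * T + eps`,
#'   `eps ~ N(0, effect_noise_sd)`.
#' @param station_density stations per million km^2 of land.
#' @param station_noise_sd observation noise of annual station temperature
#'   values, degC (precipitation noise is 20x this, mm).
#' @param north_bias hemispheric coverage bias: station intensity is
#'   proportional to `max(0, 1 + north_bias * lat / 90)`; 0 = unbiased.
#' @param years inclusive year range of station records.
#' @param missing_rate probability an individual station-year parameter
#'   value is missing.
#' @param tree_depth genealogy depth in levels (>= 1; 1 = star families).
#' @param family_mean_size mean language-family size.
#' @param disputed_frac fraction of cross-family pairs (between multi-member
#'   families) marked as having divided expert opinion (distance 9).
#' @param plant_ejectives_altitude,plant_tone_humidity optionally plant
#'   links from altitude to ejectives and from humidity to tone complexity
#'   (both off by default so trait analyses have a clean null).
#' @return object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         extent = c(-40, 40, -30, 30),
                         land_fraction_target = 0.35,
                         n_languages = 60L,
                         tropics_bias = 2,
                         min_separation_deg = 0.1,
                         raster_cell_deg = 0.5,
                         field_smoothness = 3,
                         base_temp = 27,
                         lat_gradient = 0.6,
                         lapse_per_km = 6.5,
                         noise_sd = 1.5,
                         effect_intercept = 8,
                         effect_slope = -0.15,
                         effect_noise_sd = 1.0,
                         station_density = 50,
                         station_noise_sd = 0.5,
                         north_bias = 1,
                         years = c(1951L, 1980L),
                         missing_rate = 0.02,
                         tree_depth = 3L,
                         family_mean_size = 6,
                         disputed_frac = 0.01,
                         plant_ejectives_altitude = FALSE,
                         plant_tone_humidity = FALSE) {
  stopifnot(land_fraction_target > 0, land_fraction_target < 1,
            n_languages >= 1, tropics_bias >= 0, raster_cell_deg > 0,
            field_smoothness > 0, effect_noise_sd >= 0, station_density >= 0,
            length(years) == 2, years[1] <= years[2], tree_depth >= 1,
            extent[1] < extent[2], extent[3] < extent[4])
  structure(as.list(environment()), class = "synth_config")
}

# per-stage sub-seed derived from the root seed (kept below 2^31)
derive_seed <- function(seed, stage) {
  stages <- c(world = 1L, languages = 2L, rasters = 3L, stations = 4L,
              phonologies = 5L, relatedness = 6L)
  as.integer((as.numeric(seed) * 7919 + stages[[stage]] * 104729) %% 2147483629)
}

# ---- land / sea ------------------------------------------------------------

# star-shaped blob polygon around a centre, radial wobble from a few random
# harmonics
random_blob <- function(cx, cy, r0, n_vertices = 48) {
  theta <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  wob <- rep(0, n_vertices)
  for (j in 1:4) {
    wob <- wob + stats::rnorm(1, sd = 1 / j) * sin(j * theta + stats::runif(1, 0, 2 * pi))
  }
  wob <- 0.30 * wob / max(1e-9, max(abs(wob)))
  r <- r0 * (1 + wob)
  list(list(x = cx + r * cos(theta), y = cy + r * sin(theta)))
}

#' Generate the land/sea geometry
#'
#' Land is a union of irregular star-shaped blobs added until the land
#' fraction of the extent reaches the target (the last blob is rescaled to
#' land within the tolerance).  Deterministic for a fixed config.
#'
#' @param config a [synth_config()].
#' @param tol acceptable deviation of the achieved land fraction.
#' @param max_attempts bound on blob placements before giving up.
#' @return land multipolygon (lon/lat degrees).
#' @export
make_world <- function(config, tol = 0.04, max_attempts = 300) {
  set.seed(derive_seed(config$seed, "world"))
  ext <- config$extent
  box <- rect_poly(ext[1], ext[2], ext[3], ext[4])
  box_area <- (ext[2] - ext[1]) * (ext[4] - ext[3])
  width <- ext[2] - ext[1]; height <- ext[4] - ext[3]
  land <- list()
  frac <- 0
  attempts <- 0
  while (frac < config$land_fraction_target - tol / 2) {
    attempts <- attempts + 1
    if (attempts > max_attempts) {
      stop("could not reach the target land fraction", call. = FALSE)
    }
    cx <- stats::runif(1, ext[1] + 0.05 * width, ext[2] - 0.05 * width)
    cy <- stats::runif(1, ext[3] + 0.05 * height, ext[4] - 0.05 * height)
    r0 <- 0.12 * min(width, height) * stats::runif(1, 0.6, 1.5)
    blob <- poly_intersect(random_blob(cx, cy, r0), box)
    cand <- poly_union2(land, blob)
    cand_frac <- poly_area(cand) / box_area
    if (cand_frac > config$land_fraction_target + tol) {
      # overshoot: shrink this blob about its centre to land on target
      lo <- 0; hi <- 1
      for (k in 1:20) {
        s <- (lo + hi) / 2
        shrunk <- lapply(blob, function(r) {
          list(x = cx + s * (r$x - cx), y = cy + s * (r$y - cy))
        })
        f <- poly_area(poly_union2(land, shrunk)) / box_area
        if (f > config$land_fraction_target) hi <- s else lo <- s
      }
      blob <- lapply(blob, function(r) {
        list(x = cx + hi * (r$x - cx), y = cy + hi * (r$y - cy))
      })
      cand <- poly_union2(land, blob)
      cand_frac <- poly_area(cand) / box_area
    }
    land <- cand
    frac <- cand_frac
  }
  land
}

# ---- language points -------------------------------------------------------

#' Place language points on land
#'
#' Latitudinal sampling density is proportional to
#' `exp(-tropics_bias * |lat| / 90)` (denser near the equator), longitudes
#' uniform; points are rejected off land or closer than the minimum
#' separation to an accepted point.
#'
#' @param config a [synth_config()].
#' @param land land multipolygon from [make_world()].
#' @param n number of points (default `config$n_languages`).
#' @return tibble `id`, `lon`, `lat`.
#' @export
make_languages <- function(config, land, n = config$n_languages) {
  if (poly_is_empty(land)) stop("land geometry is empty", call. = FALSE)
  set.seed(derive_seed(config$seed, "languages"))
  ext <- config$extent
  pts_lon <- numeric(0); pts_lat <- numeric(0)
  draws <- 0
  while (length(pts_lon) < n) {
    draws <- draws + 1
    if (draws > 2000) {
      stop("cannot place ", n, " points under the separation constraint",
           call. = FALSE)
    }
    m <- 4L * n
    lon <- stats::runif(m, ext[1], ext[2])
    lat <- stats::runif(m, ext[3], ext[4])
    keep <- stats::runif(m) < exp(-config$tropics_bias * abs(lat) / 90)
    lon <- lon[keep]; lat <- lat[keep]
    on_land <- points_in_polygon(lon, lat, land)
    lon <- lon[on_land]; lat <- lat[on_land]
    for (i in seq_along(lon)) {
      if (length(pts_lon) >= n) break
      if (length(pts_lon) == 0 ||
            min((pts_lon - lon[i])^2 + (pts_lat - lat[i])^2) >=
              config$min_separation_deg^2) {
        pts_lon <- c(pts_lon, lon[i]); pts_lat <- c(pts_lat, lat[i])
      }
    }
  }
  tibble::tibble(
    id = sprintf("L%03d", seq_len(n)),
    lon = pts_lon[seq_len(n)], lat = pts_lat[seq_len(n)]
  )
}

# ---- rasters ---------------------------------------------------------------

# standardized smooth Gaussian random field as an nr x nc matrix: white noise
# convolved with a separable Gaussian kernel of the given width (in cells)
smooth_field <- function(nr, nc, sigma_cells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  h <- max(1L, ceiling(3 * sigma_cells))
  kv <- stats::dnorm(0:h, sd = sigma_cells)
  smooth_mat <- function(n) {
    w <- outer(seq_len(n), seq_len(n), function(i, j) {
      d <- abs(i - j)
      out <- numeric(length(d))
      ok <- d <= h
      out[ok] <- kv[d[ok] + 1L]
      out
    })
    w / rowSums(w)
  }
  s <- smooth_mat(nr) %*% z %*% t(smooth_mat(nc))
  (s - mean(s)) / stats::sd(s)
}

#' Generate the environmental rasters
#'
#' Elevation is a smooth random field (zero at sea); temperature follows a
#' latitudinal gradient minus an elevational lapse plus smooth noise;
#' humidity, biomass and precipitation are increasing transforms of
#' temperature with their own smooth noise (hence positively inter-correlated
#' with temperature and negatively with elevation); land cover is derived
#' from biomass terciles with water and snow masks.
#'
#' @param config a [synth_config()].
#' @param land land multipolygon.
#' @return named list of [env_raster()]: `elev`, `tavg`, `tmax`, `tmin`,
#'   `qa`, `biomass`, `prcp_grid` (numeric) and `lc` (categorical), plus an
#'   attribute `lc_classes`.
#' @export
make_rasters <- function(config, land) {
  set.seed(derive_seed(config$seed, "rasters"))
  ext <- config$extent
  cell <- config$raster_cell_deg
  nc <- round((ext[2] - ext[1]) / cell)
  nr <- round((ext[4] - ext[3]) / cell)
  sig <- config$field_smoothness / cell
  lon_c <- ext[1] + (seq_len(nc) - 0.5) * cell
  lat_c <- ext[4] - (seq_len(nr) - 0.5) * cell
  lat_m <- matrix(lat_c, nr, nc)
  cc_lon <- rep(lon_c, each = nr)
  cc_lat <- rep(lat_c, times = nc)
  land_mask <- matrix(points_in_polygon(cc_lon, cc_lat, land), nr, nc)

  elev <- pmax(500 + 600 * smooth_field(nr, nc, sig), 0)
  elev[!land_mask] <- 0
  tavg <- config$base_temp - config$lat_gradient * abs(lat_m) -
    config$lapse_per_km * elev / 1000 +
    config$noise_sd * smooth_field(nr, nc, sig)
  tmax <- tavg + 8
  tmin <- tavg - 8
  qa <- pmax(0.0135 + 0.0006 * (tavg - 15) +
               0.001 * smooth_field(nr, nc, sig), 0.0005)
  biomass <- pmax(120 + 9 * (tavg - 15) + 35 * smooth_field(nr, nc, sig), 0)
  biomass[!land_mask] <- NA
  prcp <- pmax(1000 + 45 * (tavg - 15) + 250 * smooth_field(nr, nc, sig), 0)

  lc_classes <- c(tall = 1L, med = 2L, short = 3L, water = 4L, snow = 5L)
  lc <- matrix(lc_classes[["water"]], nr, nc)
  snow <- land_mask & (tavg < -5 | elev > 4000)
  veg <- land_mask & !snow
  if (any(veg)) {
    terc <- stats::quantile(biomass[veg], c(1 / 3, 2 / 3), na.rm = TRUE)
    lc[veg] <- ifelse(biomass[veg] <= terc[1], lc_classes[["short"]],
                      ifelse(biomass[veg] <= terc[2], lc_classes[["med"]],
                             lc_classes[["tall"]]))
  }
  lc[snow] <- lc_classes[["snow"]]

  mk <- function(m, kind = "numeric") {
    env_raster(m, xmin = ext[1], ymin = ext[3], cell_deg = cell, kind = kind)
  }
  out <- list(elev = mk(elev), tavg = mk(tavg), tmax = mk(tmax),
              tmin = mk(tmin), qa = mk(qa), biomass = mk(biomass),
              prcp_grid = mk(prcp), lc = mk(lc, "categorical"))
  attr(out, "lc_classes") <- lc_classes
  out
}

# ---- stations --------------------------------------------------------------

#' Generate the weather-station network and annual records
#'
#' Station locations fall on land with per-latitude intensity proportional
#' to `max(0, 1 + north_bias * lat / 90)`; each station contributes one
#' record per year in the configured range, sampling the local raster value
#' plus observation noise, with a small configurable missingness rate per
#' parameter.
#'
#' @param config a [synth_config()].
#' @param land land multipolygon.
#' @param rasters raster list from [make_rasters()].
#' @return tibble `station_id, lon, lat, year, tmin, tmax, tavg, prcp`.
#' @export
make_stations <- function(config, land, rasters) {
  set.seed(derive_seed(config$seed, "stations"))
  land_area <- poly_area_km2(land)
  n_st <- round(config$station_density * land_area / 1e6)
  years <- seq(config$years[1], config$years[2])
  if (n_st == 0L) {
    return(tibble::tibble(station_id = character(0), lon = numeric(0),
                          lat = numeric(0), year = integer(0),
                          tmin = numeric(0), tmax = numeric(0),
                          tavg = numeric(0), prcp = numeric(0)))
  }
  ext <- config$extent
  lon <- numeric(0); lat <- numeric(0)
  draws <- 0
  while (length(lon) < n_st) {
    draws <- draws + 1
    if (draws > 2000) stop("cannot place stations on land", call. = FALSE)
    m <- 4L * n_st
    cl <- stats::runif(m, ext[1], ext[2])
    ct <- stats::runif(m, ext[3], ext[4])
    w <- pmax(0, 1 + config$north_bias * ct / 90)
    keep <- stats::runif(m) < w / max(w, 1)
    cl <- cl[keep]; ct <- ct[keep]
    on_land <- points_in_polygon(cl, ct, land)
    lon <- c(lon, cl[on_land]); lat <- c(lat, ct[on_land])
  }
  st_lon <- lon[seq_len(n_st)]; st_lat <- lat[seq_len(n_st)]
  ny <- length(years)
  idx <- rep(seq_len(n_st), each = ny)
  rec_lon <- st_lon[idx]; rec_lat <- st_lat[idx]
  df <- tibble::tibble(
    station_id = sprintf("ST%04d", idx),
    lon = rec_lon, lat = rec_lat,
    year = rep(years, times = n_st),
    tmin = raster_value_at(rasters$tmin, rec_lon, rec_lat) +
      stats::rnorm(n_st * ny, sd = config$station_noise_sd),
    tmax = raster_value_at(rasters$tmax, rec_lon, rec_lat) +
      stats::rnorm(n_st * ny, sd = config$station_noise_sd),
    tavg = raster_value_at(rasters$tavg, rec_lon, rec_lat) +
      stats::rnorm(n_st * ny, sd = config$station_noise_sd),
    prcp = pmax(0, raster_value_at(rasters$prcp_grid, rec_lon, rec_lat) +
                  stats::rnorm(n_st * ny, sd = 20 * config$station_noise_sd))
  )
  if (config$missing_rate > 0) {
    for (p in c("tmin", "tmax", "tavg", "prcp")) {
      df[[p]][stats::runif(nrow(df)) < config$missing_rate] <- NA
    }
  }
  df
}

# ---- phoneme inventories ---------------------------------------------------

# decompose a latent heaviness value into integer OnsCoda (0-6) and
# CTotal (>= 6) with OnsCoda + CTotal/4 as close as possible to h; all
# feasible OnsCoda values give the same rounding error (the CTotal step is
# 0.25), so the tie-break picks the decomposition whose CTotal is nearest a
# typical inventory size of 22
decompose_cons_heavy <- function(h, ct_max = 400L) {
  oc_cand <- 0:6
  ct_cand <- pmin(ct_max, pmax(6L, round(4 * (h - oc_cand))))
  err <- abs(oc_cand + ct_cand / 4 - h)
  best <- which(err == min(err))
  pick <- best[which.min(abs(ct_cand[best] - 22L))]
  list(ons_coda = oc_cand[pick], ctotal = as.integer(ct_cand[pick]),
       clamped = min(err) > 0.25)
}

#' Generate phoneme inventories with a planted temperature effect
#'
#' The latent consonant heaviness of language i is
#' `h_i = a + b * T_i + eps_i` with `T_i` the true local mean temperature
#' read from the raster at the language point and
#' `eps ~ N(0, effect_noise_sd)`.  `h_i` is decomposed into integer OnsCoda
#' and CTotal; all remaining linguistic parameters are filled from marginal
#' distributions, independent of the environment unless the optional planted
#' links are switched on.
#'
#' @param config a [synth_config()].
#' @param languages tibble from [make_languages()].
#' @param rasters raster list from [make_rasters()].
#' @return list with `table` (full language table with derived indices) and
#'   `truth` (tibble `id, t_true, qa_true, elev_true, h_latent, clamped`).
#' @export
make_phonologies <- function(config, languages, rasters) {
  set.seed(derive_seed(config$seed, "phonologies"))
  n <- nrow(languages)
  t_true <- raster_value_at(rasters$tavg, languages$lon, languages$lat)
  qa_true <- raster_value_at(rasters$qa, languages$lon, languages$lat)
  elev_true <- raster_value_at(rasters$elev, languages$lon, languages$lat)
  h <- config$effect_intercept + config$effect_slope * t_true +
    stats::rnorm(n, sd = config$effect_noise_sd)
  dec <- lapply(h, decompose_cons_heavy)
  ons_coda <- vapply(dec, `[[`, integer(1), "ons_coda")
  ctotal <- vapply(dec, `[[`, integer(1), "ctotal")
  clamped <- vapply(dec, `[[`, logical(1), "clamped")
  if (any(clamped)) {
    warning(sum(clamped), " latent heaviness value(s) outside the feasible",
            " integer range were clamped", call. = FALSE)
  }
  onset <- integer(n); coda <- integer(n)
  for (i in seq_len(n)) {
    lo <- max(0L, ons_coda[i] - 3L)
    hi <- min(3L, ons_coda[i])
    onset[i] <- if (lo == hi) lo else sample(lo:hi, 1)
    coda[i] <- ons_coda[i] - onset[i]
  }
  vq <- sample(2:14, n, replace = TRUE,
               prob = stats::dgeom(0:12, prob = 0.25) + 0.005)
  vtotal <- pmin(72L, vq + stats::rbinom(n, 25, 0.15))
  obstr <- pmax(0L, pmin(ctotal, round(ctotal * stats::runif(n, 0.5, 0.88))))

  if (config$plant_tone_humidity) {
    z <- scale(qa_true)[, 1]
    pr <- cbind(stats::plogis(-z), 0.25, 0.25, stats::plogis(z) * 0.5)
    tone_ordinal <- apply(pr, 1, function(p) sample(0:3, 1, prob = p))
  } else {
    tone_ordinal <- sample(0:3, n, replace = TRUE,
                           prob = c(0.55, 0.2, 0.15, 0.1))
  }
  tone_cat <- character(n)
  tone_cat[tone_ordinal == 0] <- "None"
  tone_cat[tone_ordinal == 1] <- sample(c("Marginal", "Simple"),
                                        sum(tone_ordinal == 1), replace = TRUE,
                                        prob = c(0.3, 0.7))
  tone_cat[tone_ordinal == 2] <- "ModeratelyComplex"
  tone_cat[tone_ordinal == 3] <- "Complex"

  p_ej <- if (config$plant_ejectives_altitude) {
    stats::plogis(-3 + 1.6 * elev_true / 1000)
  } else rep(0.15, n)
  ejectives <- stats::runif(n) < p_ej
  n_ejectives <- ifelse(ejectives, 1L + stats::rbinom(n, 18, 0.12), 0L)
  implosives <- stats::runif(n) < 0.12
  n_implosives <- ifelse(implosives, 1L + stats::rbinom(n, 5, 0.2), 0L)
  glot_res <- stats::runif(n) < 0.06
  n_glot_res <- ifelse(glot_res, 1L + stats::rbinom(n, 7, 0.15), 0L)
  glot_c <- mapply(function(e, im, re) {
    if (!e && !im && !re) "No"
    else if (e && !im && !re) "Ej"
    else if (!e && im && !re) "Imp"
    else if (!e && !im && re) "Res"
    else if (e && im && !re) "Ej & Imp"
    else if (e && !im && re) "Ej & Res"
    else if (e && im && re) "Ej Imp & Res"
    else "Imp & Res"
  }, ejectives, implosives, glot_res)

  vow_index <- 0.45 - 0.008 * (h - mean(h)) + stats::rnorm(n, sd = 0.04)
  vow_index <- pmin(0.64, pmax(0.26, vow_index))
  vow_index[stats::runif(n) > 0.6] <- NA

  df <- tibble::tibble(
    id = languages$id,
    name = paste("Language", sub("^L", "", languages$id)),
    lon = languages$lon, lat = languages$lat,
    stable = stats::runif(n) < 0.8,
    onset = onset, coda = coda, vq = as.integer(vq),
    vtotal = as.integer(vtotal), ctotal = ctotal, obstr = as.integer(obstr),
    tone_cat = tone_cat,
    vow_index = vow_index,
    obs_lat = stats::runif(n) < 0.1,
    f_rnd_v = stats::runif(n) < 0.07,
    glot_c = unname(glot_c),
    ejectives = ejectives, n_ejectives = as.integer(n_ejectives),
    implosives = implosives, n_implosives = as.integer(n_implosives),
    glot_res = glot_res, n_glot_res = as.integer(n_glot_res),
    velar_nas = stats::runif(n) < 0.53,
    nv_pattern = sample(NV_LEVELS, n, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
    pnc = stats::runif(n) < 0.15,
    vlength = sample(VLENGTH_LEVELS, n, replace = TRUE,
                     prob = c(0.5, 0.25, 0.2, 0.05)),
    aspirates = stats::runif(n) < 0.3
  )
  df <- add_derived_indices(df)
  truth <- tibble::tibble(id = languages$id, t_true = t_true,
                          qa_true = qa_true, elev_true = elev_true,
                          h_latent = h, clamped = clamped)
  list(table = df, truth = truth)
}

# ---- genealogy -------------------------------------------------------------

#' Generate a random genealogy on the 1-10 relatedness scale
#'
#' Languages are partitioned into families; each family is given a random
#' binary branching structure up to `tree_depth` levels.  Within-family pair
#' distance is 2 plus the number of branching levels separating the pair
#' (capped at 8); a configurable fraction of cross-family pairs between
#' multi-member families is marked as disputed (9); all other cross-family
#' pairs score 10.  Singleton families are isolates.
#'
#' @param config a [synth_config()].
#' @param languages tibble from [make_languages()].
#' @return a [relatedness_table()] passing [validate_relatedness()].
#' @export
make_relatedness <- function(config, languages) {
  set.seed(derive_seed(config$seed, "relatedness"))
  ids <- sample(languages$id)
  n <- length(ids)
  sizes <- integer(0)
  while (sum(sizes) < n) {
    sizes <- c(sizes, 1L + stats::rpois(1, max(0, config$family_mean_size - 1)))
  }
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
  sizes <- sizes[sizes > 0]
  family <- rep(seq_along(sizes), times = sizes)
  # random binary split paths within each family, up to tree_depth - 1 splits
  paths <- stats::setNames(rep("", n), ids)
  for (f in seq_along(sizes)) {
    members <- ids[family == f]
    split_rec <- function(mem, level) {
      if (length(mem) < 2 || level >= config$tree_depth - 1) return(invisible())
      if (stats::runif(1) > 0.85) return(invisible())
      cut <- sample(seq_len(length(mem) - 1), 1)
      grp <- sample(mem)
      a <- grp[seq_len(cut)]; b <- grp[-seq_len(cut)]
      paths[a] <<- paste0(paths[a], "0")
      paths[b] <<- paste0(paths[b], "1")
      split_rec(a, level + 1)
      split_rec(b, level + 1)
    }
    split_rec(members, 0)
  }
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  id_i <- ids[idx[, 1]]; id_j <- ids[idx[, 2]]
  fam_i <- family[idx[, 1]]; fam_j <- family[idx[, 2]]
  d <- rep(10L, nrow(idx))
  same <- fam_i == fam_j
  if (any(same)) {
    common_prefix <- function(a, b) {
      k <- 0
      while (k < min(nchar(a), nchar(b)) &&
               substr(a, k + 1, k + 1) == substr(b, k + 1, k + 1)) k <- k + 1
      k
    }
    d[same] <- mapply(function(i, j) {
      pi_ <- paths[[i]]; pj_ <- paths[[j]]
      min(8L, 2L + max(nchar(pi_), nchar(pj_)) - common_prefix(pi_, pj_))
    }, id_i[same], id_j[same])
  }
  multi <- sizes[fam_i] >= 2 & sizes[fam_j] >= 2
  cross_multi <- which(!same & multi)
  n_disp <- round(config$disputed_frac * length(cross_multi))
  if (n_disp > 0) d[sample(cross_multi, n_disp)] <- 9L
  isolates <- ids[family %in% which(sizes == 1)]
  relatedness_table(languages$id,
                    data.frame(id_i = id_i, id_j = id_j, d = d,
                               stringsAsFactors = FALSE),
                    no_family = isolates)
}

# ---- full world ------------------------------------------------------------

#' Generate the complete synthetic world
#'
#' Runs every generator stage and bundles the results with the truth record.
#'
#' @param config a [synth_config()].
#' @return object of class `synth_world`: `config`, `land`, `languages`,
#'   `rasters` (with `lc_classes` attribute), `stations`, `language_table`,
#'   `relatedness`, `truth`.
#' @export
make_synth_world <- function(config = synth_config()) {
  land <- make_world(config)
  languages <- make_languages(config, land)
  rasters <- make_rasters(config, land)
  stations <- make_stations(config, land, rasters)
  phon <- make_phonologies(config, languages, rasters)
  relatedness <- make_relatedness(config, languages)
  structure(
    list(config = config, land = land, languages = languages,
         rasters = rasters, stations = stations,
         language_table = phon$table, relatedness = relatedness,
         truth = phon$truth),
    class = "synth_world"
  )
}

#' @export
print.synth_world <- function(x, ...) {
  cat(sprintf("<synth_world: %d languages, %d station records, %d x %d rasters, seed %d>\n",
              nrow(x$languages), nrow(x$stations),
              x$rasters$tavg$n_rows, x$rasters$tavg$n_cols, x$config$seed))
  invisible(x)
}

#' Write a synthetic world to disk in the pipeline's input formats
#'
#' Emits `languages.csv` (Table-1 layout), `stations.csv`,
#' `coastline.geojson`, one ESRI ASCII grid per raster, `relatedness.csv`
#' plus `isolates.csv`, and `truth.csv`.
#'
#' @param world a [make_synth_world()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_synth_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  f <- function(p) { files <<- c(files, p); p }
  write_language_csv(world$language_table, f(file.path(dir, "languages.csv")))
  write_station_csv(world$stations, f(file.path(dir, "stations.csv")))
  write_polygons_geojson(list(land = world$land),
                         f(file.path(dir, "coastline.geojson")))
  for (rn in names(world$rasters)) {
    write_ascii_grid(world$rasters[[rn]],
                     f(file.path(dir, paste0("raster_", rn, ".asc"))))
  }
  write_relatedness_csv(world$relatedness,
                        f(file.path(dir, "relatedness.csv")))
  utils::write.csv(data.frame(id = world$relatedness$no_family),
                   f(file.path(dir, "isolates.csv")), row.names = FALSE)
  utils::write.csv(world$truth, f(file.path(dir, "truth.csv")),
                   row.names = FALSE)
  invisible(files)
}
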