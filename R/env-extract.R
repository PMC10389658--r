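# Environmental summarization within sampling regions: annual station
# records pooled over a temporal window, zonal statistics over numeric
# rasters, per-class counts over categorical rasters, and assembly of the
# combined master table under the v_<name>_<units>__<stat> naming grammar.

#' Extraction configuration
#'
#' Temporal windows and numerical conventions used by the extraction stage.
#' Defaults: station records 1951-1980 (a 30-year span of relatively steady
#' global temperature preceding the late-20th-century acceleration, aligned
#' with climate-normal convention), humidity grids 1960-1980 (the gridded
#' humidity record begins in 1960), type-7 quartiles, strict cell-centre
#' inclusion.
#'
#' @param station_window inclusive year range for station records.
#' @param humidity_window inclusive year range for humidity grids.
#' @param quantile_type quartile algorithm for [stats::quantile()].
#' @param cell_rule cell-inclusion rule tag (only `"center"` implemented:
#'   a cell contributes iff its centre lies strictly inside the region).
#' @return object of class `extraction_config`.
#' @export
extraction_config <- function(station_window = c(1951L, 1980L),
                              humidity_window = c(1960L, 1980L),
                              quantile_type = 7,
                              cell_rule = "center") {
  stopifnot(length(station_window) == 2, station_window[1] <= station_window[2],
            length(humidity_window) == 2, humidity_window[1] <= humidity_window[2],
            identical(cell_rule, "center"))
  structure(list(station_window = as.integer(station_window),
                 humidity_window = as.integer(humidity_window),
                 quantile_type = quantile_type,
                 cell_rule = cell_rule),
            class = "extraction_config")
}

#' Filter station records to a temporal window
#'
#' @param records station data frame with a `year` column.
#' @param window inclusive year range `c(start, end)`.
#' @return the records with `window[1] <= year <= window[2]`.
#' @export
filter_station_years <- function(records, window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  records[records$year >= window[1] & records$year <= window[2], , drop = FALSE]
}

#' Summarize station records within a region
#'
#' For each parameter (tmin, tmax, tavg, prcp) pools every annual value from
#' stations whose point location lies inside the region and reports the
#' grand mean together with the number of contributing annual values (not a
#' mean of per-station means).
#'
#' @param region region polygon (lon/lat).
#' @param records station data frame: `station_id, lon, lat, year, tmin,
#'   tmax, tavg, prcp` (parameter columns may contain `NA`).
#' @return named list: for each parameter, `mean` (or `NA` if no values) and
#'   `n` (contributing annual values).
#' @export
summarize_stations <- function(region, records) {
  params <- c("tmin", "tmax", "tavg", "prcp")
  if (nrow(records) == 0) {
    return(stats::setNames(lapply(params, function(p) list(mean = NA_real_, n = 0L)),
                           params))
  }
  inside <- points_in_polygon(records$lon, records$lat, region)
  rec <- records[inside, , drop = FALSE]
  out <- lapply(params, function(p) {
    v <- rec[[p]]
    v <- v[!is.na(v)]
    list(mean = if (length(v) > 0) mean(v) else NA_real_, n = length(v))
  })
  stats::setNames(out, params)
}

#' Zonal statistics of a numeric raster within a region
#'
#' A raster cell contributes iff its centre lies strictly inside the region.
#' Reports the contributing cell count, the number of null (NA) cells inside
#' the region, and the dispersion statistics: minimum, maximum, range,
#' average, median, first and third quartile, standard deviation, sample
#' variance (n-1 denominator), and coefficient of variation (absent when the
#' average is 0).
#'
#' @param region region polygon (lon/lat).
#' @param raster a numeric [env_raster()].
#' @param quantile_type quartile algorithm (default type 7, linear
#'   interpolation between order statistics).
#' @return named list of statistics; all value statistics are `NA` when no
#'   non-null cell contributes.
#' @export
zonal_numeric <- function(region, raster, quantile_type = 7) {
  if (raster$kind != "numeric") stop("numeric raster required", call. = FALSE)
  cells <- region_cells(region, raster)
  v <- cells$value
  null_cells <- sum(is.na(v))
  v <- v[!is.na(v)]
  n <- length(v)
  if (n == 0L) {
    return(list(n = 0L, null_cells = null_cells, minimum = NA_real_,
                maximum = NA_real_, range = NA_real_, average = NA_real_,
                median = NA_real_, first_quartile = NA_real_,
                third_quartile = NA_real_, std_dev = NA_real_,
                variance = NA_real_, coeff_var = NA_real_))
  }
  avg <- mean(v)
  s <- if (n > 1) stats::sd(v) else 0
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = quantile_type, names = FALSE)
  list(
    n = n, null_cells = null_cells,
    minimum = min(v), maximum = max(v), range = max(v) - min(v),
    average = avg, median = q[2], first_quartile = q[1], third_quartile = q[3],
    std_dev = s, variance = if (n > 1) stats::var(v) else 0,
    coeff_var = if (avg != 0) s / avg else NA_real_
  )
}

# cells of a raster whose centres fall strictly inside the region
region_cells <- function(region, raster) {
  if (poly_is_empty(region)) {
    return(list(lon = numeric(0), lat = numeric(0), value = numeric(0)))
  }
  bb <- poly_bbox(region)
  cc <- raster_cell_centers(raster)
  cand <- cc$lon >= bb["xmin"] & cc$lon <= bb["xmax"] &
    cc$lat >= bb["ymin"] & cc$lat <= bb["ymax"]
  idx <- which(cand)
  if (length(idx) == 0L) {
    return(list(lon = numeric(0), lat = numeric(0), value = numeric(0)))
  }
  inside <- points_in_polygon(cc$lon[idx], cc$lat[idx], region)
  keep <- idx[inside]
  list(lon = cc$lon[keep], lat = cc$lat[keep], value = cc$value[keep])
}

#' Per-class cell counts of a categorical raster within a region
#'
#' @param region region polygon (lon/lat).
#' @param raster a categorical [env_raster()] of integer class codes.
#' @param class_map named integer vector mapping short class names to codes,
#'   e.g. `c(tall = 1, med = 2, short = 3, water = 4, snow = 5)`.
#' @return named integer vector of counts, one per class in `class_map`
#'   (absent classes are 0).  Codes present in the region but missing from
#'   `class_map` raise a warning and are reported under `"unmapped"`.
#' @export
zonal_categorical <- function(region, raster, class_map) {
  if (raster$kind != "categorical") stop("categorical raster required", call. = FALSE)
  stopifnot(!is.null(names(class_map)))
  cells <- region_cells(region, raster)
  v <- cells$value[!is.na(cells$value)]
  counts <- stats::setNames(integer(length(class_map)), names(class_map))
  for (nm in names(class_map)) counts[nm] <- sum(v == class_map[[nm]])
  unmapped <- sum(!v %in% class_map)
  if (length(v) == 0L && length(cells$value) == 0L) {
    warning("region contains no raster cells", call. = FALSE)
  }
  if (unmapped > 0) {
    warning(unmapped, " cell(s) with codes missing from class_map", call. = FALSE)
    counts <- c(counts, unmapped = unmapped)
  }
  counts
}

#' Compose an environmental variable name
#'
#' Naming grammar: `"v_" + short_name + "_" + units + "__" + stat`, e.g.
#' `v_tavg_dC__avg`, `v_elev_m__median`, `v_lc_tall_ct__sum`.
#'
#' @param short_name variable short name (may itself contain a single
#'   underscore, as in `lc_tall`).
#' @param units unit tag (`dC`, `mm`, `m`, `MgHa`, `unitless`, `ct`, ...).
#' @param stat statistic tag (`avg`, `median`, `sum`, `std_dev`,
#'   `first_quartile`, ...).
#' @return the composed variable name.
#' @details The double underscore is reserved as the units/statistic
#'   separator, so no component may contain `"__"`; the units tag may not
#'   contain an underscore at all (it must remain parseable as the token
#'   before the `"__"`).  Single underscores are legal in `short_name`
#'   (`lc_tall`) and `stat` (`std_dev`).
#' @export
name_variable <- function(short_name, units, stat) {
  if (!nzchar(units) || grepl("_", units)) {
    stop("units must be non-empty and free of underscores", call. = FALSE)
  }
  for (part in list(short_name, stat)) {
    if (!nzchar(part) || grepl("__", part)) {
      stop("name components must be non-empty and free of '__'", call. = FALSE)
    }
  }
  paste0("v_", short_name, "_", units, "__", stat)
}

# full zonal-statistic name set for one numeric raster variable
zonal_numeric_names <- function(short_name, units) {
  stats <- c(n = "n", null_cells = "null_cells", minimum = "minimum",
             maximum = "maximum", range = "range", average = "average",
             median = "median", first_quartile = "first_quartile",
             third_quartile = "third_quartile", std_dev = "std_dev",
             variance = "variance", coeff_var = "coeff_var")
  vapply(stats, function(s) name_variable(short_name, units, s), character(1))
}

#' Extract all environmental variables for every sampling region
#'
#' Runs the station summaries and the zonal statistics for each region and
#' returns one row per language under the `v_*` naming grammar.
#'
#' @param regions region tibble from [constrain_cells()].
#' @param stations station records data frame (already windowed or not; the
#'   station window of `config` is applied here).
#' @param rasters named list of [env_raster()] objects; expected names among
#'   `elev`, `qa`, `biomass`, `prcp_grid` (numeric) and `lc` (categorical).
#' @param config an [extraction_config()].
#' @param lc_classes class map for the land-cover raster.
#' @return tibble, one row per language: `language_id` plus `v_*` columns.
#' @export
extract_environment <- function(regions, stations = NULL, rasters = list(),
                                config = extraction_config(),
                                lc_classes = c(tall = 1, med = 2, short = 3,
                                               water = 4, snow = 5)) {
  if (!is.null(stations)) {
    stations <- filter_station_years(stations, config$station_window)
  }
  raster_units <- c(elev = "m", qa = "unitless", biomass = "MgHa")
  rows <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    region <- regions$polygon[[i]]
    row <- list(language_id = regions$language_id[i])
    if (!is.null(stations)) {
      st <- summarize_stations(region, stations)
      for (p in names(st)) {
        units <- if (p == "prcp") "mm" else "dC"
        row[[name_variable(p, units, "avg")]] <- st[[p]]$mean
        row[[name_variable(p, units, "n")]] <- st[[p]]$n
      }
    }
    for (rn in intersect(names(rasters), names(raster_units))) {
      z <- zonal_numeric(region, rasters[[rn]], quantile_type = config$quantile_type)
      nm <- zonal_numeric_names(rn, raster_units[[rn]])
      for (s in names(nm)) row[[nm[[s]]]] <- z[[s]]
    }
    if ("lc" %in% names(rasters)) {
      counts <- suppressWarnings(
        zonal_categorical(region, rasters$lc, lc_classes))
      for (cls in names(lc_classes)) {
        row[[name_variable(paste0("lc_", cls), "ct", "sum")]] <-
          as.integer(counts[[cls]])
      }
    }
    rows[[i]] <- tibble::as_tibble(row)
  }
  do.call(rbind, rows)
}

#' Assemble the combined master table
#'
#' One row per language joining the linguistic parameters, the region area
#' diagnostics and the environmental summaries.  Languages without a region
#' or without environmental data keep their row with empty cells (a warning
#' lists them).  Column order is stable: language columns (under their
#' Table-1 parameter names, e.g. `ConsHeavy`, `ToneOrdinal`), area
#' diagnostics, then `v_*` variables.
#'
#' @param languages language table (internal names, see
#'   [read_language_csv()]).
#' @param regions region tibble from [constrain_cells()].
#' @param env tibble from [extract_environment()].
#' @return master tibble keyed by `id`.
#' @export
assemble_master_table <- function(languages, regions, env) {
  area_cols <- tibble::tibble(
    id = regions$language_id,
    base_buffer_area_km2 = regions$base_buffer_area,
    clipped_buffer_area_km2 = regions$clipped_buffer_area,
    region_area_km2 = regions$region_area,
    inflation_ratio = regions$inflation_ratio
  )
  languages <- languages[intersect(names(LANGUAGE_CSV_COLUMNS), names(languages))]
  names(languages) <- LANGUAGE_CSV_COLUMNS[names(languages)]
  out <- merge(languages, area_cols, by = "id", all.x = TRUE, sort = FALSE)
  env2 <- env
  names(env2)[names(env2) == "language_id"] <- "id"
  out <- merge(out, env2, by = "id", all.x = TRUE, sort = FALSE)
  out <- out[match(languages$id, out$id), , drop = FALSE]
  missing_region <- languages$id[!languages$id %in% regions$language_id]
  if (length(missing_region) > 0) {
    warning("languages without a sampling region: ",
            paste(missing_region, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(out)
}

#' Read / write station records as CSV
#'
#' Layout: `station_id,lon,lat,year,tmin,tmax,tavg,prcp`; missing parameter
#' values are empty cells.
#'
#' @param path CSV file.
#' @return station tibble.
#' @export
read_station_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "lon", "lat", "year")
  stopifnot(all(need %in% names(df)))
  tibble::as_tibble(df)
}

#' @rdname read_station_csv
#' @param records station tibble to write.
#' @export
write_station_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
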