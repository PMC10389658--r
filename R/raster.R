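# Minimal in-memory raster grid for environmental fields.

#' Construct an environmental raster grid
#'
#' A lightweight regular lon/lat grid.  `values` is an `nrow x ncol` matrix
#' whose first row is the northernmost row of cells; cell centres are at
#' `xmin + (col - 0.5) * cell_deg`, `ymax - (row - 0.5) * cell_deg`.
#'
#' @param values numeric (or integer-code) matrix, row 1 = north.
#' @param xmin,ymin lower-left corner of the grid extent, degrees.
#' @param cell_deg cell size in degrees (> 0), square cells.
#' @param kind `"numeric"` or `"categorical"` (integer class codes).
#' @param crs coordinate reference tag (informational).
#' @return an object of class `env_raster`.
#' @export
env_raster <- function(values, xmin, ymin, cell_deg,
                       kind = c("numeric", "categorical"), crs = "WGS84") {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), cell_deg > 0)
  if (kind == "categorical" && !all(is.na(values) | values == round(values))) {
    stop("categorical rasters must hold integer class codes")
  }
  structure(
    list(values = values, xmin = xmin, ymin = ymin,
         cell_deg = cell_deg, n_cols = ncol(values), n_rows = nrow(values),
         kind = kind, crs = crs),
    class = "env_raster"
  )
}

#' @export
print.env_raster <- function(x, ...) {
  cat(sprintf("<env_raster %s: %d x %d cells of %g deg, origin (%g, %g)>\n",
              x$kind, x$n_rows, x$n_cols, x$cell_deg, x$xmin, x$ymin))
  invisible(x)
}

raster_ymax <- function(r) r$ymin + r$n_rows * r$cell_deg
raster_xmax <- function(r) r$xmin + r$n_cols * r$cell_deg

#' Cell-centre coordinates of a raster
#'
#' @param r an [env_raster()].
#' @return list with vectors `lon`, `lat`, `row`, `col`, `value` in
#'   row-major order (north to south).
#' @export
raster_cell_centers <- function(r) {
  col <- rep(seq_len(r$n_cols), times = r$n_rows)
  row <- rep(seq_len(r$n_rows), each = r$n_cols)
  list(
    lon = r$xmin + (col - 0.5) * r$cell_deg,
    lat = raster_ymax(r) - (row - 0.5) * r$cell_deg,
    row = row, col = col,
    value = as.vector(t(r$values))
  )
}

#' Raster value at point locations (nearest cell)
#'
#' @param r an [env_raster()].
#' @param lon,lat point coordinates in degrees.
#' @return numeric vector; `NA` for points off the grid.
#' @export
raster_value_at <- function(r, lon, lat) {
  col <- floor((lon - r$xmin) / r$cell_deg) + 1L
  row <- floor((raster_ymax(r) - lat) / r$cell_deg) + 1L
  ok <- col >= 1L & col <= r$n_cols & row >= 1L & row <= r$n_rows
  out <- rep(NA_real_, length(lon))
  out[ok] <- r$values[cbind(row[ok], col[ok])]
  out
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by standard GIS tools.
#'
#' @param r an [env_raster()].
#' @param path output file.
#' @param nodata value used to encode `NA` cells.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", r$n_cols),
    sprintf("nrows %d", r$n_rows),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", r$cell_deg),
    sprintf("NODATA_value %g", nodata)
  ), con)
  v <- r$values
  v[is.na(v)] <- nodata
  for (i in seq_len(nrow(v))) {
    writeLines(paste(format(v[i, ], digits = 10, trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()] or any ESRI ASCII raster.
#' @param kind `"numeric"` or `"categorical"`.
#' @return an [env_raster()].
#' @export
read_ascii_grid <- function(path, kind = "numeric") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- hdr$nodata_value
  if (!is.null(nodata)) m[m == nodata] <- NA
  xmin <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - hdr$cellsize / 2
  ymin <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - hdr$cellsize / 2
  env_raster(m, xmin = xmin, ymin = ymin, cell_deg = hdr$cellsize, kind = kind)
}
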