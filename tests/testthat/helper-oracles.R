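# Shared fixtures and independent oracles.  The oracles deliberately avoid
# the package's own geometry/statistics code paths: point-in-polygon is a
# hand-written ray-casting loop, zonal statistics are a per-cell loop with
# explicit formulas, and quantiles are computed by direct linear
# interpolation between order statistics.

.world_cache <- new.env(parent = emptyenv())

# memoize synthetic worlds: several test files share the same fixtures
cached_world <- function(seed = 42, ...) {
  key <- paste(seed, paste(unlist(list(...)), collapse = "_"), sep = "_")
  if (is.null(.world_cache[[key]])) {
    .world_cache[[key]] <- make_synth_world(synth_config(seed = seed, ...))
  }
  .world_cache[[key]]
}

# independent even-odd ray-casting point-in-polygon test
oracle_point_in_poly <- function(px, py, poly) {
  vapply(seq_along(px), function(k) {
    crossings <- 0L
    for (ring in poly) {
      n <- length(ring$x)
      j <- n
      for (i in seq_len(n)) {
        yi <- ring$y[i]; yj <- ring$y[j]
        if ((yi > py[k]) != (yj > py[k])) {
          xint <- ring$x[i] + (py[k] - yi) / (yj - yi) * (ring$x[j] - ring$x[i])
          if (px[k] < xint) crossings <- crossings + 1L
        }
        j <- i
      }
    }
    crossings %% 2L == 1L
  }, logical(1))
}

# direct linear interpolation between order statistics (the "type 7" rule)
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[pmin(lo + 2, n)] - s[lo + 1])
}

# brute-force zonal statistics: explicit per-cell loop with its own
# inclusion test and moment formulas
oracle_zonal <- function(region, raster) {
  vals <- numeric(0)
  nulls <- 0L
  ymax <- raster$ymin + raster$n_rows * raster$cell_deg
  for (row in seq_len(raster$n_rows)) {
    for (col in seq_len(raster$n_cols)) {
      cx <- raster$xmin + (col - 0.5) * raster$cell_deg
      cy <- ymax - (row - 0.5) * raster$cell_deg
      if (oracle_point_in_poly(cx, cy, region)) {
        v <- raster$values[row, col]
        if (is.na(v)) nulls <- nulls + 1L else vals <- c(vals, v)
      }
    }
  }
  n <- length(vals)
  if (n == 0L) return(list(n = 0L, null_cells = nulls))
  m <- sum(vals) / n
  va <- if (n > 1) sum((vals - m)^2) / (n - 1) else 0
  list(n = n, null_cells = nulls, minimum = min(vals), maximum = max(vals),
       range = max(vals) - min(vals), average = m,
       median = oracle_quantile(vals, 0.5),
       first_quartile = oracle_quantile(vals, 0.25),
       third_quartile = oracle_quantile(vals, 0.75),
       std_dev = sqrt(va), variance = va,
       coeff_var = if (m != 0) sqrt(va) / m else NA_real_)
}

# random simple polygon for zonal tests: convex hull of random points
random_region <- function(xr, yr, n_pts = 8) {
  x <- runif(n_pts, xr[1], xr[2])
  y <- runif(n_pts, yr[1], yr[2])
  h <- grDevices::chull(x, y)
  list(list(x = x[h], y = y[h]))
}
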