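#' Define a regular latitude-longitude grid
#'
#' Cells are `res`-degree squares. Rows run north to south, columns west to
#' east; cell ids are row-major integers. All downstream geometry (cell
#' membership, centroids, rasters) refers to one of these grid objects.
#'
#' @param lat_range,lon_range Numeric length-2 bounds in degrees.
#' @param res Cell size in degrees (> 0, must divide both extents).
#' @return An object of class `sg_grid`.
#' @export
make_grid <- function(lat_range = c(-60, 60), lon_range = c(-30, 30), res = 1) {
  stopifnot(res > 0, diff(lat_range) > 0, diff(lon_range) > 0)
  n_lat <- diff(lat_range) / res
  n_lon <- diff(lon_range) / res
  if (abs(n_lat - round(n_lat)) > 1e-9 || abs(n_lon - round(n_lon)) > 1e-9) {
    stop("resolution must divide the lat and lon extents")
  }
  n_lat <- as.integer(round(n_lat)); n_lon <- as.integer(round(n_lon))
  structure(list(
    lat_range = lat_range, lon_range = lon_range, res = res,
    n_lat = n_lat, n_lon = n_lon, n_cells = n_lat * n_lon,
    # centroids: row 1 = northernmost band
    lat = lat_range[2] - res * (seq_len(n_lat) - 0.5),
    lon = lon_range[1] + res * (seq_len(n_lon) - 0.5)
  ), class = "sg_grid")
}

#' @export
print.sg_grid <- function(x, ...) {
  cat(sprintf("sg_grid: %d x %d cells of %g deg (lat %g..%g, lon %g..%g)\n",
              x$n_lat, x$n_lon, x$res, x$lat_range[1], x$lat_range[2],
              x$lon_range[1], x$lon_range[2]))
  invisible(x)
}

#' Cell centroids of a grid
#'
#' @param grid An `sg_grid`.
#' @param cells Optional integer cell ids (default: all cells).
#' @return `data.frame` with columns `cell`, `lon`, `lat`.
#' @export
cell_centroids <- function(grid, cells = seq_len(grid$n_cells)) {
  row <- (cells - 1L) %/% grid$n_lon + 1L
  col <- (cells - 1L) %% grid$n_lon + 1L
  data.frame(cell = cells, lon = grid$lon[col], lat = grid$lat[row])
}

# row/col <-> cell id helpers
cell_id <- function(grid, row, col) (row - 1L) * grid$n_lon + col
cell_rowcol <- function(grid, cells) {
  cbind(row = (cells - 1L) %/% grid$n_lon + 1L,
        col = (cells - 1L) %% grid$n_lon + 1L)
}

# 4-neighbourhood of cells on the grid (no wraparound)
cell_neighbors <- function(grid, cells) {
  rc <- cell_rowcol(grid, cells)
  out <- integer(0)
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    r <- rc[, "row"] + d[1]; c <- rc[, "col"] + d[2]
    ok <- r >= 1L & r <= grid$n_lat & c >= 1L & c <= grid$n_lon
    out <- c(out, cell_id(grid, r[ok], c[ok]))
  }
  unique(out)
}

#' Simulate contiguous species ranges on a grid (spreading dye)
#'
#' Each species receives a target range size drawn from a configurable
#' right-skewed distribution (most ranges small, few large, as in empirical
#' range-size frequency distributions), an anchor cell, and then grows a
#' contiguous cell set by repeatedly annexing a random cell adjacent to the
#' current range. Optional latitudinal anchoring concentrates chosen species
#' at target latitudes, which is how planted geographic rate gradients are
#' built.
#'
#' @param species Character vector of species names.
#' @param grid An `sg_grid`.
#' @param size_dist `"lognormal"` (default) or `"geometric"`.
#' @param meanlog,sdlog Lognormal parameters of the range-size distribution
#'   (in cells).
#' @param prob Success probability for the geometric alternative.
#' @param anchor_lat Optional numeric vector (length 1 or `length(species)`)
#'   of target anchor latitudes in degrees; `NA` entries anchor uniformly at
#'   random.
#' @param anchor_sd Standard deviation (degrees) of the Gaussian scatter
#'   around `anchor_lat`.
#' @param anchor_cell Optional integer vector of explicit anchor cells
#'   (length 1 or `length(species)`); overrides `anchor_lat` where not `NA`.
#' @param seed Optional integer seed.
#' @return Named list mapping species to sorted integer cell-id vectors.
#' @export
simulate_ranges <- function(species, grid, size_dist = c("lognormal", "geometric"),
                            meanlog = log(12), sdlog = 0.8, prob = 0.08,
                            anchor_lat = NULL, anchor_sd = 5,
                            anchor_cell = NULL, seed = NULL) {
  size_dist <- match.arg(size_dist)
  if (!is.null(seed)) set.seed(seed)
  n <- length(species)
  sizes <- switch(size_dist,
    lognormal = pmax(1L, round(stats::rlnorm(n, meanlog, sdlog))),
    geometric = 1L + stats::rgeom(n, prob)
  )
  if (any(sizes > grid$n_cells)) {
    sizes <- pmin(sizes, grid$n_cells)
  }
  if (!is.null(anchor_lat)) anchor_lat <- rep_len(anchor_lat, n)
  if (!is.null(anchor_cell)) anchor_cell <- rep_len(as.integer(anchor_cell), n)
  ranges <- vector("list", n); names(ranges) <- species
  for (i in seq_len(n)) {
    start <- if (!is.null(anchor_cell) && !is.na(anchor_cell[i])) {
      anchor_cell[i]
    } else {
      pick_anchor_cell(grid, if (is.null(anchor_lat)) NA else anchor_lat[i],
                       anchor_sd)
    }
    ranges[[i]] <- spread_dye(grid, start, sizes[i])
  }
  ranges
}

pick_anchor_cell <- function(grid, target_lat, anchor_sd) {
  if (is.na(target_lat)) {
    return(sample.int(grid$n_cells, 1L))
  }
  lat <- stats::rnorm(1L, target_lat, anchor_sd)
  lat <- min(max(lat, grid$lat_range[1] + grid$res / 2),
             grid$lat_range[2] - grid$res / 2)
  row <- which.min(abs(grid$lat - lat))
  col <- sample.int(grid$n_lon, 1L)
  cell_id(grid, row, col)
}

spread_dye <- function(grid, start, size) {
  range <- start
  if (size <= 1L) return(range)
  in_range <- logical(grid$n_cells); in_range[start] <- TRUE
  frontier <- setdiff(cell_neighbors(grid, start), start)
  while (length(range) < size && length(frontier) > 0L) {
    nxt <- frontier[sample.int(length(frontier), 1L)]
    range <- c(range, nxt); in_range[nxt] <- TRUE
    nb <- cell_neighbors(grid, nxt)
    frontier <- unique(c(frontier[frontier != nxt], nb[!in_range[nb]]))
  }
  sort(range)
}

#' Simulate a multi-horizon stack of smooth climate rasters
#'
#' Each variable at each time horizon is a deterministic south-to-north
#' linear spatial gradient plus a linear temporal trend, plus optional
#' smooth spatial noise. With `noise_sd = 0` the climate-change velocity of
#' the stack has the closed form `(trend_per_kyr / 1000) / gradient_per_km`
#' km/yr everywhere, which anchors the velocity tests.
#'
#' @param grid An `sg_grid`.
#' @param horizon_ages Ages of the time horizons in years before present;
#'   must start at 0 (current conditions).
#' @param n_vars Number of climate variables.
#' @param gradient_per_km Spatial gradient, units per km of northing
#'   (recycled over variables).
#' @param trend_per_kyr Temporal trend, units per 1000 years of age
#'   (recycled over variables).
#' @param noise_sd Standard deviation of smooth spatial noise (0 = off).
#' @param noise_scale Gaussian smoothing radius of the noise, in cells.
#' @param km_per_deg Kilometres per degree of latitude.
#' @param seed Optional integer seed.
#' @return A list of class `climate_stack`: `vars` is a list (one per
#'   variable) of lists of rasters (matrices, one per horizon);
#'   `horizon_ages`, `grid`, `km_per_deg` are recorded alongside.
#' @export
simulate_climate_stack <- function(grid, horizon_ages = c(0, 1e5, 1e6, 3e6),
                                   n_vars = 3, gradient_per_km = 0.05,
                                   trend_per_kyr = 0.002, noise_sd = 0,
                                   noise_scale = 3, km_per_deg = 111.32,
                                   seed = NULL) {
  stopifnot(length(horizon_ages) >= 2, horizon_ages[1] == 0)
  if (grid$n_lat < 2 || grid$n_lon < 2) stop("degenerate grid for climate stack")
  if (!is.null(seed)) set.seed(seed)
  gradient_per_km <- rep_len(gradient_per_km, n_vars)
  trend_per_kyr <- rep_len(trend_per_kyr, n_vars)
  northing_km <- matrix(grid$lat * km_per_deg, grid$n_lat, grid$n_lon)
  vars <- vector("list", n_vars)
  for (v in seq_len(n_vars)) {
    noise <- if (noise_sd > 0) {
      smooth_field(matrix(stats::rnorm(grid$n_cells), grid$n_lat, grid$n_lon),
                   noise_scale) * noise_sd
    } else 0
    vars[[v]] <- lapply(horizon_ages, function(age) {
      gradient_per_km[v] * northing_km + trend_per_kyr[v] * (age / 1000) + noise
    })
  }
  structure(list(vars = vars, horizon_ages = horizon_ages, grid = grid,
                 km_per_deg = km_per_deg), class = "climate_stack")
}

# Gaussian-kernel smoothing by separable 1D convolution, replicate-padded.
smooth_field <- function(m, scale) {
  if (scale <= 0) return(m)
  half <- max(1L, ceiling(3 * scale))
  k <- stats::dnorm(seq(-half, half), sd = scale)
  k <- k / sum(k)
  conv1 <- function(x) { # along rows of a matrix, replicate padding
    n <- nrow(x)
    pad <- rbind(x[rep(1L, half), , drop = FALSE], x,
                 x[rep(n, half), , drop = FALSE])
    out <- matrix(0, n, ncol(x))
    for (j in seq_along(k)) out <- out + k[j] * pad[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(m))))
}

#' Simulate a smoothed random elevation field
#'
#' White noise smoothed with a Gaussian kernel and scaled so that the field's
#' standard deviation equals `relief_sd`; `relief_sd = 0` gives a flat
#' surface (roughness 0 everywhere).
#'
#' @param grid An `sg_grid`.
#' @param relief_sd Standard deviation of the field in elevation units (m).
#' @param smooth_scale Gaussian smoothing radius in cells; larger = gentler
#'   terrain.
#' @param seed Optional integer seed.
#' @return A `n_lat x n_lon` matrix.
#' @export
simulate_elevation <- function(grid, relief_sd = 300, smooth_scale = 1.5,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (relief_sd == 0) return(matrix(0, grid$n_lat, grid$n_lon))
  f <- smooth_field(matrix(stats::rnorm(grid$n_cells), grid$n_lat, grid$n_lon),
                    smooth_scale)
  f * (relief_sd / stats::sd(as.vector(f)))
}

#' Partition a grid into contiguous Voronoi bioregions with predictor tables
#'
#' Seeds `n` cells at random and assigns every cell to the nearest seed
#' (great-circle distance between centroids), yielding a contiguous
#' Voronoi-like partition. Each region gets a table of supplied predictors
#' (time-integrated area, productivity, temperature) drawn from fixed
#' right-skewed / Gaussian distributions, standing in for externally
#' provided historical reconstructions.
#'
#' @param grid An `sg_grid`.
#' @param n Number of bioregions (>= 2).
#' @param seed Optional integer seed.
#' @return A list of class `bioregions`: `region` (integer vector over all
#'   cells), `n`, `predictors` (data.frame with region, time_integrated_area,
#'   productivity, temperature), `centroids` (per-region mean lon/lat).
#' @export
partition_bioregions <- function(grid, n = 16, seed = NULL) {
  stopifnot(n >= 2, n <= grid$n_cells)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(grid$n_cells, n)
  cc <- cell_centroids(grid)
  sc <- cc[seeds, ]
  d <- gc_distance_deg(cbind(cc$lon, cc$lat), cbind(sc$lon, sc$lat))
  region <- max.col(-d) # nearest seed
  predictors <- data.frame(
    region = seq_len(n),
    time_integrated_area = stats::rlnorm(n, log(1e6), 0.6),
    productivity = stats::rlnorm(n, log(1000), 0.5),
    temperature = stats::rnorm(n, 15, 8)
  )
  centroids <- data.frame(
    region = seq_len(n),
    lon = as.vector(tapply(cc$lon, region, mean)),
    lat = as.vector(tapply(cc$lat, region, mean))
  )
  structure(list(region = region, n = n, predictors = predictors,
                 centroids = centroids, grid = grid), class = "bioregions")
}

# great-circle central angle in degrees between rows of a (lon, lat) matrix
# and rows of another; returns |A| x |B| matrix
gc_distance_deg <- function(a, b = a) {
  rad <- pi / 180
  la1 <- a[, 2] * rad; lo1 <- a[, 1] * rad
  la2 <- b[, 2] * rad; lo2 <- b[, 1] * rad
  # haversine, vectorised via outer
  dlat <- outer(la1, la2, "-")
  dlon <- outer(lo1, lo2, "-")
  h <- sin(dlat / 2)^2 + outer(cos(la1), cos(la2)) * sin(dlon / 2)^2
  h[h > 1] <- 1; h[h < 0] <- 0
  2 * asin(sqrt(h)) / rad
}
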