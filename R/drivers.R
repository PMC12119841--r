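#' Slope magnitude of a raster surface (3x3 average-maximum technique)
#'
#' Computes the spatial gradient magnitude of a raster by the standard 3x3
#' average-maximum (Horn) stencil: the east-west and north-south partial
#' derivatives are weighted differences of the 3x3 neighbourhood
#' (weights 1-2-1), and the slope is their Euclidean norm. Edge cells use
#' linearly extrapolated border values, so a linear ramp has its exact
#' constant gradient everywhere including the border.
#'
#' @param r Numeric matrix (rows = north to south).
#' @param cellsize_km Cell size in km (same in both axes).
#' @return Matrix of gradient magnitudes, units of `r` per km.
#' @export
slope_surface <- function(r, cellsize_km) {
  stopifnot(nrow(r) >= 2, ncol(r) >= 2, cellsize_km > 0)
  p <- pad_linear(r)
  nr <- nrow(r); nc <- ncol(r)
  sub <- function(dr, dc) p[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  # column index grows eastward, row index grows southward
  dzdx <- ((sub(0, 2) + 2 * sub(1, 2) + sub(2, 2)) -
           (sub(0, 0) + 2 * sub(1, 0) + sub(2, 0))) / (8 * cellsize_km)
  dzdy <- ((sub(2, 0) + 2 * sub(2, 1) + sub(2, 2)) -
           (sub(0, 0) + 2 * sub(0, 1) + sub(0, 2))) / (8 * cellsize_km)
  sqrt(dzdx^2 + dzdy^2)
}

pad_replicate <- function(r) {
  r2 <- rbind(r[1, , drop = FALSE], r, r[nrow(r), , drop = FALSE])
  cbind(r2[, 1, drop = FALSE], r2, r2[, ncol(r2), drop = FALSE])
}

# pad by linear extrapolation of the border (2*edge - next): exact for
# linear ramps, used by the gradient stencil
pad_linear <- function(r) {
  n <- nrow(r); m <- ncol(r)
  r2 <- rbind(2 * r[1, , drop = FALSE] - r[2, , drop = FALSE], r,
              2 * r[n, , drop = FALSE] - r[n - 1, , drop = FALSE])
  cbind(2 * r2[, 1, drop = FALSE] - r2[, 2, drop = FALSE], r2,
        2 * r2[, m, drop = FALSE] - r2[, m - 1, drop = FALSE])
}

#' Climate-change velocity between two time horizons
#'
#' The local velocity of climate displacement: the temporal rate of change
#' `|current - past| / dt` (units per year) divided by the spatial gradient
#' of the current surface (units per km), giving km/yr -- how fast a point
#' would have to move to keep its climate constant. Cells with zero spatial
#' gradient have undefined velocity and are returned `NA` (excluded from
#' any later averaging rather than capped).
#'
#' @param current,past Numeric matrices on the same grid.
#' @param dt_years Time separation in years (> 0).
#' @param cellsize_km Cell size in km.
#' @return Matrix of velocities (km/yr), `NA` where undefined;
#'   `attr(,"n_undefined")` counts flagged cells.
#' @export
climate_velocity <- function(current, past, dt_years, cellsize_km) {
  stopifnot(all(dim(current) == dim(past)), dt_years > 0)
  temporal <- abs(current - past) / dt_years
  spatial <- slope_surface(current, cellsize_km)
  v <- temporal / spatial
  v[spatial == 0] <- NA_real_
  attr(v, "n_undefined") <- sum(spatial == 0)
  v
}

#' Mean climate-change velocity of a multi-variable, multi-horizon stack
#'
#' Computes [climate_velocity()] for every past horizon against current
#' conditions, averages over horizons, then combines variables by the
#' arithmetic mean (median available). This is the per-cell summary used as
#' the historical climate-instability predictor.
#'
#' @param stack A `climate_stack` from [simulate_climate_stack()] (or any
#'   list with `vars`, `horizon_ages`, `grid`, `km_per_deg`).
#' @param combine `"mean"` (default) or `"median"` across variables.
#' @return Matrix of mean velocities (km/yr), `NA` where undefined.
#' @export
velocity_field <- function(stack, combine = c("mean", "median")) {
  combine <- match.arg(combine)
  ages <- stack$horizon_ages
  if (length(ages) < 2) stop("need at least one past horizon")
  cellsize_km <- stack$grid$res * stack$km_per_deg
  per_var <- lapply(stack$vars, function(horizons) {
    current <- horizons[[1]]
    vs <- lapply(seq_along(ages)[-1], function(h) {
      climate_velocity(current, horizons[[h]], dt_years = ages[h],
                       cellsize_km = cellsize_km)
    })
    Reduce(`+`, vs) / length(vs)
  })
  arr <- simplify2array(per_var)
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1)
  apply(arr, c(1, 2), match.fun(combine))
}

#' Terrain roughness (3x3 max - min)
#'
#' Per-cell difference between the maximum and minimum value over the cell
#' and its eight neighbours, the usual topographic-complexity proxy. Edge
#' cells use their available neighbours.
#'
#' @param elevation Numeric matrix (>= 3 rows and columns).
#' @return Matrix of the same shape, in elevation units.
#' @export
roughness <- function(elevation) {
  if (nrow(elevation) < 3 || ncol(elevation) < 3) stop("raster must be >= 3x3")
  p <- pad_replicate(elevation)
  nr <- nrow(elevation); nc <- ncol(elevation)
  mx <- matrix(-Inf, nr, nc); mn <- matrix(Inf, nr, nc)
  for (dr in 0:2) for (dc in 0:2) {
    s <- p[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
    mx <- pmax(mx, s); mn <- pmin(mn, s)
  }
  mx - mn
}

#' Average a raster over bioregions
#'
#' @param r Numeric matrix on the bioregions' grid (cells in row-major
#'   order match `regions$region`).
#' @param regions A `bioregions` object.
#' @param na.rm Drop undefined cells (default TRUE; e.g. undefined
#'   velocities).
#' @return Named numeric vector, one value per region.
#' @export
region_mean <- function(r, regions, na.rm = TRUE) {
  vals <- as.vector(t(r)) # row-major cell order (row 1 west->east first)
  if (length(vals) != length(regions$region)) {
    stop("raster does not match the bioregion grid")
  }
  out <- tapply(vals, regions$region, mean, na.rm = na.rm)
  if (anyNA(out) || any(!seq_len(regions$n) %in% names(out))) {
    stop("region with no (defined) raster cells")
  }
  out[as.character(seq_len(regions$n))]
}

#' Net relatedness index per cell and per bioregion
#'
#' For every occupied cell with at least two species, computes the observed
#' mean pairwise patristic distance (MPD) among the co-occurring species and
#' compares it to a null built by shuffling tip identities within the
#' regional species pool (all species occurring anywhere in the cell's
#' bioregion). The shuffle keeps the presence-absence matrix fixed, so the
#' observed richness pattern and range-size frequency distribution are
#' preserved exactly. `NRI = -(MPD_obs - mean(MPD_null)) / sd(MPD_null)`;
#' positive values indicate phylogenetic clustering. The regional value is
#' the mean over that region's scored cells.
#'
#' @param ag An `assemblage_grid` whose species are all tips of `tree`.
#' @param tree A rooted `phylo` (patristic distances are precomputed once).
#' @param regions A `bioregions` object on the same grid.
#' @param n_rand Number of null shuffles (default 999).
#' @param seed Optional integer seed.
#' @return A list: `per_cell` (data.frame cell, region, richness, mpd_obs,
#'   nri), `per_region` (named vector), `n_skipped` (richness < 2 cells),
#'   `n_degenerate` (cells with zero null sd, returned `NA`).
#' @export
nri <- function(ag, tree, regions, n_rand = 999, seed = NULL) {
  miss <- setdiff(colnames(ag$pam), tree$tip.label)
  if (length(miss) > 0) {
    stop("species not on the tree: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  D <- ape::cophenetic.phylo(tree)[colnames(ag$pam), colnames(ag$pam)]
  cell_region <- regions$region[ag$cells]
  pools <- lapply(seq_len(regions$n), function(rg) {
    rows <- which(cell_region == rg)
    if (length(rows) == 0) return(integer(0))
    which(colSums(ag$pam[rows, , drop = FALSE]) > 0)
  })
  mpd_of <- function(idx) {
    k <- length(idx)
    (sum(D[idx, idx])) / (k * (k - 1))
  }
  score <- ag$richness >= 2
  res <- data.frame(cell = ag$cells, region = cell_region,
                    richness = unname(ag$richness),
                    mpd_obs = NA_real_, nri = NA_real_)
  n_degenerate <- 0L
  for (i in which(score)) {
    members <- which(ag$pam[i, ] == 1L)
    pool <- pools[[cell_region[i]]]
    k <- length(members)
    obs <- mpd_of(members)
    nulls <- vapply(seq_len(n_rand), function(j) {
      mpd_of(pool[sample.int(length(pool), k)])
    }, numeric(1))
    s <- stats::sd(nulls)
    res$mpd_obs[i] <- obs
    if (s == 0) {
      n_degenerate <- n_degenerate + 1L
    } else {
      res$nri[i] <- -(obs - mean(nulls)) / s
    }
  }
  per_region <- tapply(res$nri[score], res$region[score], mean, na.rm = TRUE)
  out <- stats::setNames(rep(NA_real_, regions$n), seq_len(regions$n))
  out[names(per_region)] <- per_region
  list(per_cell = res, per_region = out,
       n_skipped = sum(!score), n_degenerate = n_degenerate)
}

#' Assemble the bioregion-level response and predictor table
#'
#' Joins the per-region mean speciation rate (mean over member cells of the
#' cell-level mean DR) with the six predictors: supplied time-integrated
#' area, productivity and temperature, plus computed climatic velocity,
#' roughness and NRI. Predictors are z-standardised (standardised copies in
#' `*_z` columns) so model coefficients are comparable effect sizes. A
#' constant predictor is an error; near-collinear predictor pairs
#' (|r| > 0.95) raise a warning.
#'
#' @param summaries Cell summaries from [cell_summaries()].
#' @param regions A `bioregions` object.
#' @param velocity Per-region velocity (named vector from [region_mean()]).
#' @param rough Per-region roughness.
#' @param nri_region Per-region NRI.
#' @return `data.frame` of class `bioregion_table`: region, lon, lat,
#'   mean_rate, n_cells, six raw predictors and their `_z` copies.
#' @export
assemble_bioregion_table <- function(summaries, regions, velocity, rough,
                                     nri_region) {
  cell_region <- regions$region[summaries$cell]
  mean_rate <- tapply(summaries$mean_rate, cell_region, mean)
  n_cells <- tapply(summaries$mean_rate, cell_region, length)
  keep <- sort(as.integer(names(mean_rate)))
  tab <- data.frame(
    region = keep,
    lon = regions$centroids$lon[keep],
    lat = regions$centroids$lat[keep],
    mean_rate = as.vector(mean_rate[as.character(keep)]),
    n_cells = as.vector(n_cells[as.character(keep)]),
    time_integrated_area = regions$predictors$time_integrated_area[keep],
    productivity = regions$predictors$productivity[keep],
    temperature = regions$predictors$temperature[keep],
    climatic_velocity = as.vector(velocity[as.character(keep)]),
    roughness = as.vector(rough[as.character(keep)]),
    nri = as.vector(nri_region[as.character(keep)])
  )
  pred <- c("time_integrated_area", "productivity", "temperature",
            "climatic_velocity", "roughness", "nri")
  # regions with no scorable community (every cell below richness 2, or all
  # null sds degenerate) have no NRI: excluded from the model sample
  no_nri <- !is.finite(tab$nri)
  if (any(no_nri)) {
    message(sum(no_nri), " region(s) dropped: no defined NRI (no cell with >= 2 species)")
    tab <- tab[!no_nri, , drop = FALSE]
  }
  if (anyNA(tab[pred])) {
    bad <- pred[vapply(tab[pred], anyNA, logical(1))]
    stop("missing predictor values at model time: ", paste(bad, collapse = ", "))
  }
  for (p in pred) {
    s <- stats::sd(tab[[p]])
    if (s == 0) stop("constant predictor dropped: ", p)
    tab[[paste0(p, "_z")]] <- (tab[[p]] - mean(tab[[p]])) / s
  }
  cm <- stats::cor(tab[pred])
  high <- which(abs(cm) > 0.95 & upper.tri(cm), arr.ind = TRUE)
  if (nrow(high) > 0) {
    warning("collinear predictors (|r| > 0.95): ",
            paste(apply(high, 1, function(ij)
              paste(pred[ij[1]], pred[ij[2]], sep = " ~ ")), collapse = ", "))
  }
  class(tab) <- c("bioregion_table", "data.frame")
  tab
}

#' Fit the six-predictor spatial-error driver model
#'
#' Regresses bioregion mean speciation rate on the six standardised
#' predictors with a spatial-error term, choosing the neighbourhood cutoff
#' by AIC over a 10-100 degree ladder, and reports the Nagelkerke
#' pseudo-R-squared against the intercept-only spatial null on the same
#' weights.
#'
#' @param table A `bioregion_table`.
#' @param cutoffs Candidate cutoffs in degrees.
#' @param power,row_standardize Passed to [build_weights()].
#' @return A list: `fit` (`sar_error_fit`), `null_fit`, `best_cutoff`,
#'   `cutoff_table`, `nagelkerke_r2`, `effects` (coefficient table with
#'   95% CI and significance flag), `ols` (baseline `ols_fit`).
#' @export
run_driver_model <- function(table, cutoffs = seq(10, 100, by = 10),
                             power = 2, row_standardize = TRUE) {
  if (nrow(table) < 10) stop("need at least 10 bioregions to fit the driver model")
  predz <- paste0(c("time_integrated_area", "productivity", "temperature",
                    "climatic_velocity", "roughness", "nri"), "_z")
  X <- as.matrix(table[predz])
  y <- table$mean_rate
  coords <- as.matrix(table[, c("lon", "lat")])
  sel <- select_cutoff(X, y, coords, cutoffs = cutoffs, power = power,
                       row_standardize = row_standardize)
  w <- suppressWarnings(build_weights(coords, sel$best_cutoff, power = power,
                                      row_standardize = row_standardize))
  fit <- sel$best_fit
  null_fit <- fit_sar_error(matrix(numeric(0), nrow = length(y), ncol = 0),
                            y, w)
  r2 <- nagelkerke_r2(fit, null_fit)
  cf <- fit$coefficients
  effects <- data.frame(
    predictor = rownames(cf),
    estimate = cf$Estimate,
    ci_lo = cf$Estimate - 1.96 * cf$Std.Error,
    ci_hi = cf$Estimate + 1.96 * cf$Std.Error,
    z = cf$z, p = cf$p,
    significant = cf$p < 0.05
  )
  list(fit = fit, null_fit = null_fit, best_cutoff = sel$best_cutoff,
       cutoff_table = sel$table, nagelkerke_r2 = r2, effects = effects,
       ols = fit_ols(X, y))
}
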