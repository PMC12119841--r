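#' Build the cells x species presence-absence matrix
#'
#' Assembles gridded species ranges into a presence-absence matrix (PAM).
#' Ranges are native cell sets on the grid, so presence is exact: a species
#' occupies a cell iff the cell is in its range (this matches the
#' "any overlap" rule for polygon sources, where touching a cell counts as
#' presence). Cells occupied by no species are dropped, with the count
#' reported. If a rate table is supplied, species missing from it are
#' excluded with a warning (the intersection step between range data and
#' phylogeny).
#'
#' @param ranges Named list mapping species to integer cell-id vectors.
#' @param grid The `sg_grid` the cell ids refer to.
#' @param rates Optional `tip_rate_table`; species absent from it are
#'   dropped from the PAM and reported.
#' @return An object of class `assemblage_grid`: `grid`, `cells` (retained
#'   ids), `pam` (binary cells x species matrix with dimnames), `richness`,
#'   `n_dropped_cells`, `excluded_species`.
#' @export
build_pam <- function(ranges, grid, rates = NULL) {
  if (length(ranges) == 0) stop("no ranges supplied")
  sizes <- lengths(ranges)
  if (any(sizes == 0)) {
    stop("empty range for: ", paste(names(ranges)[sizes == 0], collapse = ", "))
  }
  excluded <- character(0)
  if (!is.null(rates)) {
    excluded <- setdiff(names(ranges), rates$species)
    if (length(excluded) > 0) {
      warning(length(excluded), " species have ranges but no rates; excluded: ",
              paste(utils::head(excluded, 5), collapse = ", "),
              if (length(excluded) > 5) ", ...")
      ranges <- ranges[setdiff(names(ranges), excluded)]
      if (length(ranges) == 0) stop("no species left after rate intersection")
    }
  }
  species <- names(ranges)
  occ_cells <- sort(unique(unlist(ranges, use.names = FALSE)))
  if (any(occ_cells < 1L | occ_cells > grid$n_cells)) {
    stop("range cell ids outside the grid")
  }
  pam <- matrix(0L, length(occ_cells), length(species),
                dimnames = list(as.character(occ_cells), species))
  for (j in seq_along(species)) {
    pam[match(ranges[[j]], occ_cells), j] <- 1L
  }
  n_dropped <- grid$n_cells - length(occ_cells)
  structure(list(
    grid = grid, cells = occ_cells, pam = pam,
    richness = rowSums(pam), n_dropped_cells = n_dropped,
    excluded_species = excluded
  ), class = "assemblage_grid")
}

#' @export
print.assemblage_grid <- function(x, ...) {
  cat(sprintf("assemblage_grid: %d occupied cells x %d species (%d empty cells dropped)\n",
              nrow(x$pam), ncol(x$pam), x$n_dropped_cells))
  invisible(x)
}

#' Per-cell speciation-rate summaries
#'
#' For every occupied cell, summarises the tip rates of the co-occurring
#' species: arithmetic mean, maximum, and the coefficient of variation in
#' percent (100 x sample sd / mean), the heterogeneity measure that is
#' insensitive to richness differences among cells. CV is undefined
#' (returned `NA`) for cells with a single species.
#'
#' @param ag An `assemblage_grid`.
#' @param rates A `tip_rate_table` covering every species in the PAM.
#' @return `data.frame` with columns `cell`, `lon`, `lat`, `abs_lat`,
#'   `richness`, `mean_rate`, `max_rate`, `cv_rate`.
#' @export
cell_summaries <- function(ag, rates) {
  miss <- setdiff(colnames(ag$pam), rates$species)
  if (length(miss) > 0) {
    stop("PAM species without rates: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  r <- rates$dr_mean[match(colnames(ag$pam), rates$species)]
  pam <- ag$pam
  k <- ag$richness
  s1 <- as.vector(pam %*% r)
  s2 <- as.vector(pam %*% r^2)
  mean_rate <- s1 / k
  # sample variance from sums; guard tiny negative round-off
  var_rate <- ifelse(k > 1, pmax(0, (s2 - s1^2 / k) / (k - 1)), NA_real_)
  cv_rate <- 100 * sqrt(var_rate) / mean_rate
  max_rate <- vapply(seq_len(nrow(pam)), function(i) max(r[pam[i, ] == 1L]),
                     numeric(1))
  cc <- cell_centroids(ag$grid, ag$cells)
  data.frame(cell = ag$cells, lon = cc$lon, lat = cc$lat,
             abs_lat = abs(cc$lat), richness = unname(k),
             mean_rate = unname(mean_rate), max_rate = max_rate,
             cv_rate = unname(cv_rate))
}

#' Classify species as tropical or non-tropical by range latitudinal midpoint
#'
#' The latitudinal midpoint of a species is the area-weighted mean latitude
#' of its occupied cell centroids (weights proportional to cos(latitude),
#' the relative area of equal-degree cells); a bounding-box midpoint is
#' available as an alternative. Species with |midpoint| at or below the
#' tropic line (23.44 degrees, Tropics of Cancer/Capricorn) are classed
#' tropical; the boundary is inclusive.
#'
#' @param ranges Named list of integer cell-id vectors.
#' @param grid The `sg_grid` the cells refer to.
#' @param method `"area"` (default, cos-weighted centroid) or `"bbox"`
#'   (midpoint of the latitudinal extent).
#' @param boundary Tropic latitude in degrees (default 23.44).
#' @return `data.frame` with columns `species`, `midpoint`, `class`
#'   (factor tropical/non-tropical).
#' @export
classify_latitude <- function(ranges, grid, method = c("area", "bbox"),
                              boundary = 23.44) {
  method <- match.arg(method)
  if (any(lengths(ranges) == 0)) stop("empty range(s)")
  mid <- vapply(ranges, function(cells) {
    lat <- cell_centroids(grid, cells)$lat
    switch(method,
      area = stats::weighted.mean(lat, w = cos(lat * pi / 180)),
      bbox = (min(lat) + max(lat)) / 2)
  }, numeric(1))
  cls <- ifelse(abs(mid) <= boundary, "tropical", "non-tropical")
  data.frame(species = names(ranges), midpoint = unname(mid),
             class = factor(cls, levels = c("tropical", "non-tropical")))
}

#' Restrict an assemblage grid to one taxonomic group
#'
#' Drops all species outside the named group and removes cells left empty,
#' so rate surfaces can be recomputed per clade (the deconstruction of a
#' class-wide pattern into its orders).
#'
#' @param ag An `assemblage_grid`.
#' @param taxon_map Named character vector: species -> group label. Every
#'   PAM species must be present.
#' @param group Group label to keep.
#' @return A new `assemblage_grid` restricted to the group.
#' @export
order_subset <- function(ag, taxon_map, group) {
  if (!group %in% taxon_map) stop("unknown group label: ", group)
  miss <- setdiff(colnames(ag$pam), names(taxon_map))
  if (length(miss) > 0) {
    stop("species without a group assignment: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  keep_sp <- colnames(ag$pam)[taxon_map[colnames(ag$pam)] == group]
  if (length(keep_sp) == 0) stop("group '", group, "' has no species in the PAM")
  pam <- ag$pam[, keep_sp, drop = FALSE]
  keep_cells <- rowSums(pam) > 0
  pam <- pam[keep_cells, , drop = FALSE]
  structure(list(
    grid = ag$grid, cells = ag$cells[keep_cells], pam = pam,
    richness = rowSums(pam),
    n_dropped_cells = ag$n_dropped_cells + sum(!keep_cells),
    excluded_species = ag$excluded_species
  ), class = "assemblage_grid")
}

#' Export a PAM as a long-format CSV (cell_id, species)
#'
#' @param ag An `assemblage_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pam <- function(ag, path) {
  idx <- which(ag$pam == 1L, arr.ind = TRUE)
  out <- data.frame(cell_id = ag$cells[idx[, 1]],
                    species = colnames(ag$pam)[idx[, 2]])
  out <- out[order(out$cell_id, out$species), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
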