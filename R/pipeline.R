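#' Run the full analysis pipeline on a synthetic or loaded world
#'
#' Sequences the complete analysis: (1) tip rates aggregated over the tree
#' posterior, (2) presence-absence gridding and per-cell rate summaries,
#' (3) spatial-error regression of cell mean rate on absolute latitude
#' (5-degree cutoff, inverse-square weights) with OLS baseline and
#' Nagelkerke pseudo-R-squared, (4) tropical / non-tropical classification
#' at 23.44 degrees and the batch state-dependent speciation test over the
#' posterior, (5) bioregion drivers: climate velocity, roughness, NRI,
#' merged with supplied predictors into the six-predictor spatial-error
#' model with AIC cutoff selection. Identical world + seed gives identical
#' outputs; if `out_dir` is set, every stage writes a self-describing CSV
#' plus a JSON manifest.
#'
#' @param world An `sg_world` from [simulate_world()] (or a `world_config`,
#'   which is simulated first).
#' @param lat_cutoff Connectivity cutoff (degrees) of the latitude model.
#' @param driver_cutoffs Candidate cutoffs for the driver model AIC scan.
#' @param n_null Null simulations per tree for the state-dependent test.
#' @param n_fisse_trees Number of posterior trees used in the test batch
#'   (default: all).
#' @param n_rand NRI randomisations.
#' @param seed Seed for the analysis-stage randomness (null traits, NRI
#'   shuffles); defaults to the world's seed.
#' @param out_dir Optional output directory for CSV artefacts + manifest.
#' @return A list of class `sg_pipeline`: `rates`, `ag`, `summaries`,
#'   `lat_model` (list fit/ols/null_fit/nagelkerke_r2/weights),
#'   `latitude_classes`, `fisse` (batch result or NULL if one class),
#'   `drivers` (list velocity/roughness/nri/table/model), `manifest`.
#' @export
sg_run_pipeline <- function(world, lat_cutoff = 5,
                            driver_cutoffs = seq(10, 100, by = 10),
                            n_null = 200, n_fisse_trees = NULL,
                            n_rand = 199, seed = NULL, out_dir = NULL) {
  if (inherits(world, "world_config")) world <- simulate_world(world)
  if (!inherits(world, "sg_world")) stop("world must be an sg_world or world_config")
  if (is.null(seed)) seed <- world$config$seed

  rates <- aggregate_posterior(world$posterior)
  ag <- build_pam(world$ranges, world$grid, rates)
  summ <- cell_summaries(ag, rates)

  # latitude gradient model on cell mean rates
  coords <- as.matrix(summ[, c("lon", "lat")])
  w <- suppressWarnings(build_weights(coords, lat_cutoff, power = 2))
  ev <- weights_eigenvalues(w)
  X <- cbind(abs_lat = summ$abs_lat)
  fit <- fit_sar_error(X, summ$mean_rate, w, ev = ev)
  null_fit <- fit_sar_error(matrix(numeric(0), nrow(summ), 0),
                            summ$mean_rate, w, ev = ev)
  lat_model <- list(fit = fit, ols = fit_ols(X, summ$mean_rate),
                    null_fit = null_fit,
                    nagelkerke_r2 = nagelkerke_r2(fit, null_fit),
                    weights = w)

  # tropical vs non-tropical state-dependent test (state 1 = non-tropical)
  classes <- classify_latitude(world$ranges[colnames(ag$pam)], world$grid)
  traits <- stats::setNames(as.integer(classes$class == "non-tropical"),
                            classes$species)
  fisse <- NULL
  if (length(unique(traits)) == 2L) {
    trees <- world$posterior
    if (!is.null(n_fisse_trees)) trees <- trees[seq_len(min(n_fisse_trees, length(trees)))]
    trees <- lapply(trees, ape::keep.tip, tip = names(traits))
    fisse <- fisse_batch(trees, traits, n_null = n_null, seed = seed)
  }

  # bioregion drivers
  vel_cell <- velocity_field(world$climate)
  rough_cell <- roughness(world$elevation)
  vel <- region_mean(vel_cell, world$bioregions)
  rough <- region_mean(rough_cell, world$bioregions)
  nri_res <- nri(ag, world$tree, world$bioregions, n_rand = n_rand,
                 seed = seed + 1L)
  table <- assemble_bioregion_table(summ, world$bioregions, vel, rough,
                                    nri_res$per_region)
  model <- run_driver_model(table, cutoffs = driver_cutoffs)
  drivers <- list(velocity_cell = vel_cell, roughness_cell = rough_cell,
                  velocity = vel, roughness = rough, nri = nri_res,
                  table = table, model = model)

  manifest <- list(
    package = "speciogeo",
    version = as.character(utils::packageVersion("speciogeo")),
    created = format(Sys.time(), tz = "UTC"),
    seed = seed, world_seed = world$config$seed,
    plant = world$config$plant,
    n_species = length(world$tree$tip.label),
    n_posterior = length(world$posterior),
    n_cells = nrow(ag$pam), n_bioregions = world$bioregions$n,
    lat_cutoff = lat_cutoff, n_null = n_null, n_rand = n_rand,
    driver_best_cutoff = model$best_cutoff,
    config = unclass(world$config)
  )
  out <- structure(list(rates = rates, ag = ag, summaries = summ,
                        lat_model = lat_model, latitude_classes = classes,
                        fisse = fisse, drivers = drivers,
                        manifest = manifest),
                   class = "sg_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' @export
print.sg_pipeline <- function(x, ...) {
  sl <- x$lat_model$fit$coefficients["abs_lat", ]
  cat("pipeline run:", x$manifest$n_species, "species,",
      x$manifest$n_cells, "cells,", x$manifest$n_bioregions, "bioregions\n")
  cat(sprintf("  mean rate ~ |lat|: slope %.4g (p = %.3g), pseudo-R2 = %.3f, OLS adj R2 = %.3f\n",
              sl$Estimate, sl$p, x$lat_model$nagelkerke_r2, x$lat_model$ols$adj_r2))
  if (!is.null(x$fisse)) {
    cat(sprintf("  tropical vs non-tropical: mean lambda0 = %.4g, lambda1 = %.4g, mean p = %.3g\n",
                x$fisse$mean_lambda0, x$fisse$mean_lambda1, x$fisse$mean_p))
  }
  eff <- x$drivers$model$effects
  sig <- eff$predictor[eff$significant & eff$predictor != "(Intercept)"]
  cat(sprintf("  driver model: cutoff %g deg, Nagelkerke R2 = %.3f, significant: %s\n",
              x$drivers$model$best_cutoff, x$drivers$model$nagelkerke_r2,
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
  invisible(x)
}

# CSV + manifest writer; every file is a plain rectangular table
write_pipeline <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  write_tip_rates(x$rates, file.path(out_dir, "tip_rates.csv"))
  write_pam(x$ag, file.path(out_dir, "pam.csv"))
  wcsv(x$summaries, "cell_summaries.csv")
  cf <- x$lat_model$fit$coefficients
  wcsv(data.frame(term = rownames(cf), cf,
                  adj_r2_ols = x$lat_model$ols$adj_r2,
                  pseudo_r2 = x$lat_model$nagelkerke_r2,
                  lambda_spatial = x$lat_model$fit$lambda),
       "latitude_sar.csv")
  wcsv(x$latitude_classes, "latitude_classes.csv")
  if (!is.null(x$fisse)) wcsv(x$fisse$per_tree, "fisse_per_tree.csv")
  wcsv(as.data.frame(x$drivers$table), "bioregion_table.csv")
  wcsv(x$drivers$model$effects, "driver_effects.csv")
  wcsv(x$drivers$model$cutoff_table, "driver_cutoff_scan.csv")
  jsonlite::write_json(x$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
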