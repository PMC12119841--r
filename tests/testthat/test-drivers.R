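test_that("roughness matches hand values and the nested-loop oracle", {
  expect_true(all(roughness(matrix(5, 4, 4)) == 0))
  m <- matrix(1:9, 3, 3, byrow = TRUE)
  expect_equal(roughness(m)[2, 2], 8)
  set.seed(111)
  r <- matrix(rnorm(50 * 50), 50, 50)
  expect_equal(roughness(r), oracle_roughness(r), tolerance = 0)
  expect_error(roughness(matrix(1, 2, 2)), "3x3")
})

test_that("climate velocity matches its closed form and stencil oracle", {
  # ramp of 1 unit/km; 1 unit change over 1000 years -> 0.001 km/yr
  cell_km <- 2
  cur <- matrix(rep((1:10) * cell_km, 12), 10, 12)
  past <- cur - 1
  v <- climate_velocity(cur, past, dt_years = 1000, cellsize_km = cell_km)
  expect_equal(as.vector(v), rep(0.001, 120), tolerance = 1e-12)
  # past = current -> zero velocity
  v0 <- climate_velocity(cur, cur, dt_years = 1000, cellsize_km = cell_km)
  expect_true(all(v0 == 0))
  # flat current surface: undefined everywhere, flagged
  flat <- matrix(3, 5, 5)
  vf <- climate_velocity(flat, flat - 1, 100, 1)
  expect_true(all(is.na(vf)))
  expect_equal(attr(vf, "n_undefined"), 25)
  # random smooth fields vs the brute-force stencil
  set.seed(131)
  for (i in 1:3) {
    n <- sample(10:50, 1); m <- sample(10:50, 1)
    cur <- speciogeo:::smooth_field(matrix(rnorm(n * m), n, m), 2)
    past <- cur + speciogeo:::smooth_field(matrix(rnorm(n * m), n, m), 2) * 0.1
    got <- climate_velocity(cur, past, 500, 1.7)
    want <- oracle_velocity(cur, past, 500, 1.7)
    expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("region means respect the partition and flag empty regions", {
  g <- make_grid(c(0, 6), c(0, 6), res = 1)
  br <- partition_bioregions(g, n = 4, seed = 5)
  r <- matrix(seq_len(g$n_cells), g$n_lat, g$n_lon, byrow = TRUE)
  rm <- region_mean(r, br)
  # every cell contributes to exactly one region
  expect_equal(sum(rm * tabulate(br$region, 4)), sum(r))
  allna <- matrix(NA_real_, g$n_lat, g$n_lon)
  expect_error(region_mean(allna, br), "no \\(defined\\)")
})

test_that("NRI finds planted clustering and is invariant to branch scaling", {
  set.seed(151)
  tr <- simulate_bd_tree(0.4, 0, 24)
  g <- make_grid(c(0, 6), c(0, 8), res = 2)
  br <- partition_bioregions(g, n = 2, seed = 9)
  # community of two sister tips against a large pool: clustered, NRI > 0
  d <- ape::cophenetic.phylo(tr)
  sisters <- which(d == min(d[d > 0]), arr.ind = TRUE)[1, ]
  sp <- tr$tip.label
  ranges <- stats::setNames(lapply(sp, function(s) sample.int(g$n_cells, 3)), sp)
  ranges[[sp[sisters[1]]]] <- 1L
  ranges[[sp[sisters[2]]]] <- 1L
  for (i in setdiff(seq_along(sp), sisters)) {
    ranges[[i]] <- setdiff(ranges[[i]], 1L)
    if (length(ranges[[i]]) == 0) ranges[[i]] <- 2L
  }
  ag <- build_pam(ranges, g)
  res <- nri(ag, tr, br, n_rand = 499, seed = 33)
  cell1 <- res$per_cell[res$per_cell$cell == 1L, ]
  expect_equal(cell1$mpd_obs, d[sisters[1], sisters[2]])
  expect_gt(cell1$nri, 1)
  # doubling branch lengths doubles MPDs but leaves the z-score unchanged
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 2
  res2 <- nri(ag, tr2, br, n_rand = 499, seed = 33)
  expect_equal(res2$per_cell$mpd_obs, 2 * res$per_cell$mpd_obs, tolerance = 1e-12)
  expect_equal(res2$per_cell$nri, res$per_cell$nri, tolerance = 1e-9)
  expect_equal(res2$per_region, res$per_region, tolerance = 1e-9)
})

test_that("observed MPD agrees with the picante reference implementation", {
  skip_if_not_installed("picante")
  set.seed(163)
  tr <- simulate_bd_tree(0.3, 0, 20)
  g <- make_grid(c(0, 4), c(0, 10), res = 2)
  br <- partition_bioregions(g, n = 2, seed = 3)
  ranges <- random_ranges(tr$tip.label, g, p_occ = 0.3)
  ag <- build_pam(ranges, g)
  res <- nri(ag, tr, br, n_rand = 99, seed = 1)
  comm <- ag$pam
  rownames(comm) <- as.character(ag$cells)
  ref <- picante::mpd(comm, ape::cophenetic.phylo(tr)[colnames(comm), colnames(comm)])
  scored <- ag$richness >= 2
  expect_equal(res$per_cell$mpd_obs[scored], ref[scored], tolerance = 1e-10)
})

test_that("degenerate pools give flagged, not numeric, NRI", {
  tr <- toy_tree("((A:1,B:1):1,(C:1,D:1):1);")
  g <- make_grid(c(0, 2), c(0, 4), res = 2)
  br <- partition_bioregions(g, n = 2, seed = 2)
  # region pool of exactly the two occurring species: null sd is zero
  ranges <- list(A = 1L, B = 1L)
  ag <- build_pam(ranges, g)
  res <- nri(ag, tr, br, n_rand = 99, seed = 4)
  expect_true(is.na(res$per_cell$nri[1]))
  expect_equal(res$n_degenerate, 1L)
})

test_that("the bioregion table standardises predictors and screens pathologies", {
  set.seed(167)
  w <- simulate_world(world_config(plant = "drivers", n_species = 80,
                                   n_bioregions = 12, res = 4,
                                   lon_range = c(-32, 32), seed = 21))
  rates <- aggregate_posterior(w$posterior)
  ag <- build_pam(w$ranges, w$grid, rates)
  summ <- cell_summaries(ag, rates)
  vel <- region_mean(velocity_field(w$climate), w$bioregions)
  rough <- region_mean(roughness(w$elevation), w$bioregions)
  nr <- nri(ag, w$tree, w$bioregions, n_rand = 99, seed = 8)
  tab <- suppressMessages(assemble_bioregion_table(summ, w$bioregions, vel,
                                                   rough, nr$per_region))
  zc <- grep("_z$", names(tab), value = TRUE)
  expect_length(zc, 6)
  for (z in zc) {
    expect_equal(mean(tab[[z]]), 0, tolerance = 1e-12)
    expect_equal(stats::sd(tab[[z]]), 1, tolerance = 1e-12)
  }
  # constant predictor is fatal
  w2 <- w; w2$bioregions$predictors$temperature <- 7
  expect_error(
    suppressMessages(assemble_bioregion_table(summ, w2$bioregions, vel, rough,
                                              nr$per_region)),
    "constant predictor")
  # near-duplicate predictors trigger the collinearity screen
  w3 <- w
  w3$bioregions$predictors$productivity <-
    w3$bioregions$predictors$temperature * 2 +
    stats::rnorm(12, 0, 1e-4)
  expect_warning(
    suppressMessages(assemble_bioregion_table(summ, w3$bioregions, vel, rough,
                                              nr$per_region)),
    "collinear")
})
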