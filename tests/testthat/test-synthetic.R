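test_that("birth-death simulation is deterministic, ultrametric and exact in tip count", {
  t1 <- simulate_bd_tree(0.5, 0.1, 40, seed = 99)
  t2 <- simulate_bd_tree(0.5, 0.1, 40, seed = 99)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(ape::Ntip(t1), 40)
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  expect_error(simulate_bisse_tree(0.1, 0.1, 0, n_tips = 5, mu = 0.2),
               "extinction rate")
})

test_that("two-tip crown age follows the exponential closed form", {
  # with 2 crown lineages at rate lambda each, the stopping rule puts the
  # present at an Exp(2 lambda) waiting time
  set.seed(101)
  depths <- replicate(400, {
    tr <- simulate_bd_tree(1, 0, 2)
    max(ape::node.depth.edgelength(tr))
  })
  ks <- suppressWarnings(stats::ks.test(depths, "pexp", rate = 2))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(depths), 0.5, tolerance = 0.15)
})

test_that("state-dependent simulation honours its limiting cases", {
  # q = 0 from a state-0 root: trait never flips
  res <- simulate_bisse_tree(0.5, 0.5, q = 0, n_tips = 20, seed = 4)
  expect_true(all(res$states == 0))
  # equal rates: a neutral trait on a plain birth-death tree, both states reachable
  res2 <- simulate_bisse_tree(0.5, 0.5, q = 0.5, n_tips = 50, seed = 5)
  expect_setequal(sort(unique(res2$states)), c(0, 1))
  expect_true(ape::is.ultrametric(res2$tree, tol = 1e-8))
  # faster state accumulates higher tip rates in most replicates (small batch;
  # the full calibration lives with the acceptance checks)
  set.seed(6)
  wins <- replicate(25, {
    r <- simulate_bisse_tree(0.1, 0.2, q = 0.03, n_tips = 60)
    lam <- state_lambda(r$tree, r$states)
    lam["lambda1"] > lam["lambda0"]
  })
  expect_gt(mean(wins), 0.7)
})

test_that("spreading-dye ranges are contiguous with the requested sizes", {
  grid <- make_grid(c(-10, 10), c(-10, 10), res = 2)
  r1 <- simulate_ranges("sp1", grid, meanlog = 0, sdlog = 0, seed = 1)
  expect_length(r1$sp1, 1)
  # whole-grid ranges give richness = n_species everywhere
  rall <- lapply(1:3, function(i) seq_len(grid$n_cells))
  names(rall) <- paste0("s", 1:3)
  ag <- build_pam(rall, grid)
  expect_true(all(ag$richness == 3))
  # contiguity: a range's cells form one 4-connected component
  set.seed(2)
  rng <- simulate_ranges(paste0("x", 1:30), grid, meanlog = log(8), sdlog = 0.6)
  for (cells in rng) {
    comp <- cells[1]
    repeat {
      nb <- intersect(speciogeo:::cell_neighbors(grid, comp), cells)
      new <- setdiff(nb, comp)
      if (length(new) == 0) break
      comp <- c(comp, new)
    }
    expect_setequal(comp, cells)
  }
})

test_that("climate stacks have the advertised closed-form structure", {
  grid <- make_grid(c(0, 10), c(0, 10), res = 1)
  st <- simulate_climate_stack(grid, horizon_ages = c(0, 1000), n_vars = 1,
                               gradient_per_km = 1, trend_per_kyr = 1,
                               noise_sd = 0)
  # 1 unit/km gradient, 1 unit/kyr trend -> 0.001 km/yr everywhere
  v <- velocity_field(st)
  expect_equal(as.vector(v), rep(0.001, grid$n_cells), tolerance = 1e-12)
  expect_error(simulate_climate_stack(grid, horizon_ages = c(100, 200)))
})

test_that("flat elevation gives zero roughness and bioregions partition the grid", {
  grid <- make_grid(c(-30, 30), c(-60, 60), res = 1)
  flat <- simulate_elevation(grid, relief_sd = 0)
  expect_true(all(roughness(flat) == 0))
  br <- partition_bioregions(grid, n = 32, seed = 8)
  expect_length(br$region, grid$n_cells)
  expect_setequal(unique(br$region), 1:32)
  expect_equal(nrow(br$predictors), 32)
})

test_that("whole worlds are reproducible and exportable as text", {
  cfg <- world_config(n_species = 40, n_posterior = 3, lon_range = c(-12, 12),
                      res = 4, n_bioregions = 4, seed = 77)
  w1 <- simulate_world(cfg)
  w2 <- simulate_world(cfg)
  expect_identical(ape::write.tree(w1$tree), ape::write.tree(w2$tree))
  expect_identical(w1$ranges, w2$ranges)
  expect_identical(w1$elevation, w2$elevation)
  expect_true(all(lengths(w1$ranges) >= 1))
  d <- withr::local_tempdir()
  write_world(w1, d)
  expect_true(all(file.exists(file.path(d, c(
    "posterior.nwk", "ranges.csv", "clades.csv", "bioregion_cells.csv",
    "bioregion_predictors.csv", "elevation.csv")))))
  expect_length(read_newick_set(file.path(d, "posterior.nwk")), 3)
})
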