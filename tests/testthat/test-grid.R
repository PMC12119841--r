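test_that("presence-absence assembly matches hand cases and conserves occupancy", {
  grid <- make_grid(c(0, 4), c(0, 4), res = 2)
  ag1 <- build_pam(list(a = 1L), grid)
  expect_equal(dim(ag1$pam), c(1, 1))
  expect_equal(unname(ag1$pam[1, 1]), 1L)
  ag2 <- build_pam(list(a = 1L, b = 4L), grid)
  expect_equal(unname(ag2$pam), diag(2))
  expect_equal(ag2$n_dropped_cells, 2)
  # conservation: total richness equals total range size, exactly
  set.seed(31)
  g <- make_grid(c(-20, 20), c(-20, 20), res = 2)
  rng <- simulate_ranges(paste0("s", 1:60), g, meanlog = log(6), sdlog = 0.8)
  ag <- build_pam(rng, g)
  expect_equal(sum(ag$richness), sum(lengths(rng)))
  expect_error(build_pam(list(a = integer(0)), g), "empty range")
})

test_that("PAM equals a brute-force cell-by-cell overlap oracle", {
  set.seed(17)
  g <- make_grid(c(0, 20), c(0, 20), res = 1) # 20 x 20
  rng <- simulate_ranges(paste0("s", 1:50), g, meanlog = log(5), sdlog = 1)
  ag <- build_pam(rng, g)
  oracle <- matrix(0L, length(ag$cells), length(rng),
                   dimnames = dimnames(ag$pam))
  for (i in seq_along(ag$cells)) {
    for (j in seq_along(rng)) {
      oracle[i, j] <- as.integer(ag$cells[i] %in% rng[[j]])
    }
  }
  expect_identical(ag$pam, oracle)
  # cells outside every range were dropped
  expect_setequal(ag$cells, sort(unique(unlist(rng))))
})

test_that("species without rates are excluded with a warning", {
  grid <- make_grid(c(0, 4), c(0, 4), res = 2)
  rates <- data.frame(species = c("a", "b"), dr_mean = c(1, 2))
  expect_warning(ag <- build_pam(list(a = 1L, b = 2L, zz = 3L), grid, rates),
                 "no rates")
  expect_setequal(colnames(ag$pam), c("a", "b"))
  expect_identical(ag$excluded_species, "zz")
})

test_that("cell summaries compute mean, max and percent CV as defined", {
  grid <- make_grid(c(0, 2), c(0, 2), res = 2)
  rates <- data.frame(species = c("a", "b", "c"), dr_mean = c(1, 1, 1))
  ag <- build_pam(list(a = 1L, b = 1L, c = 1L), grid)
  s <- cell_summaries(ag, rates)
  expect_equal(s$mean_rate, 1); expect_equal(s$max_rate, 1)
  expect_equal(s$cv_rate, 0)

  rates2 <- data.frame(species = c("a", "b"), dr_mean = c(1, 3))
  ag2 <- build_pam(list(a = 1L, b = 1L), grid)
  s2 <- cell_summaries(ag2, rates2)
  expect_equal(s2$mean_rate, 2); expect_equal(s2$max_rate, 3)
  expect_equal(s2$cv_rate, 100 * sqrt(2) / 2, tolerance = 1e-12)

  # richness-1 cells: mean = the single rate, CV undefined
  ag3 <- build_pam(list(a = 1L), grid)
  s3 <- cell_summaries(ag3, rates2)
  expect_equal(s3$mean_rate, 1)
  expect_true(is.na(s3$cv_rate))
})

test_that("CV is scale-invariant and the >30 percent flag separates mixed cells", {
  set.seed(41)
  g <- make_grid(c(-10, 10), c(-10, 10), res = 2)
  rng <- simulate_ranges(paste0("s", 1:30), g, meanlog = log(6), sdlog = 0.7)
  rates <- data.frame(species = names(rng), dr_mean = runif(30, 0.05, 0.5))
  ag <- build_pam(rng, g)
  s1 <- cell_summaries(ag, rates)
  rates10 <- rates; rates10$dr_mean <- rates10$dr_mean * 10
  s2 <- cell_summaries(ag, rates10)
  expect_equal(s2$cv_rate, s1$cv_rate, tolerance = 1e-12)
  expect_equal(s2$mean_rate, 10 * s1$mean_rate, tolerance = 1e-12)
  # a planted half-fast half-slow assemblage exceeds the 30% CV flag,
  # a homogeneous one stays under it
  mixed <- data.frame(species = c("a", "b", "c", "d"),
                      dr_mean = c(0.1, 0.1, 0.4, 0.4))
  agm <- build_pam(list(a = 1L, b = 1L, c = 1L, d = 1L),
                   make_grid(c(0, 2), c(0, 2), res = 2))
  expect_gt(cell_summaries(agm, mixed)$cv_rate, 30)
  homo <- mixed; homo$dr_mean <- c(0.30, 0.31, 0.30, 0.29)
  expect_lt(cell_summaries(agm, homo)$cv_rate, 30)
  # constant-rate world: constant mean surface
  rc <- data.frame(species = names(rng), dr_mean = rep(0.2, 30))
  expect_equal(cell_summaries(ag, rc)$mean_rate, rep(0.2, nrow(ag$pam)))
})

test_that("latitudinal midpoint classification uses the inclusive 23.44 boundary", {
  g <- make_grid(c(-50, 50), c(0, 10), res = 1)
  eq_cell <- speciogeo:::cell_id(g, which(abs(g$lat - 0.5) < 1e-9), 1L)
  mid_cell <- speciogeo:::cell_id(g, which(abs(g$lat - 45.5) < 1e-9), 1L)
  cls <- classify_latitude(list(eq = eq_cell, high = mid_cell), g)
  expect_equal(as.character(cls$class), c("tropical", "non-tropical"))
  # centroid exactly on the tropic line -> tropical (inclusive)
  gb <- make_grid(c(23.44 - 0.5, 23.44 + 0.5), c(0, 1), res = 1)
  clb <- classify_latitude(list(border = 1L), gb)
  expect_equal(clb$midpoint, 23.44)
  expect_equal(as.character(clb$class), "tropical")
  # bounding-box option
  g2 <- make_grid(c(0, 4), c(0, 1), res = 1)
  span <- classify_latitude(list(s = c(1L, 4L)), g2, method = "bbox")
  expect_equal(span$midpoint, 2)
})

test_that("order subsets conserve richness across a partition", {
  set.seed(53)
  g <- make_grid(c(-10, 10), c(-10, 10), res = 2)
  rng <- simulate_ranges(paste0("s", 1:30), g, meanlog = log(5), sdlog = 0.6)
  ag <- build_pam(rng, g)
  groups <- stats::setNames(sample(c("anura", "caudata", "gymno"), 30, TRUE),
                            names(rng))
  subs <- lapply(unique(groups), function(gr) order_subset(ag, groups, gr))
  total <- rep(0, length(ag$cells)); names(total) <- as.character(ag$cells)
  for (s in subs) total[as.character(s$cells)] <- total[as.character(s$cells)] + s$richness
  expect_equal(unname(total), unname(ag$richness))
  # identity and single-species cases
  all_grp <- stats::setNames(rep("all", 30), names(rng))
  expect_equal(order_subset(ag, all_grp, "all")$pam, ag$pam)
  one <- stats::setNames(c("one", rep("rest", 29)), names(rng))
  expect_setequal(order_subset(ag, one, "one")$cells, rng[[1]])
  expect_error(order_subset(ag, groups, "nope"), "unknown group")
})
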