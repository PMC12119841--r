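test_that("distance-band weights match hand values and the double-loop oracle", {
  two <- rbind(c(0, 0), c(0, 1)) # 1 degree apart on a meridian
  w <- build_weights(two, cutoff_deg = 5, row_standardize = FALSE)
  expect_equal(w$W, matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  far <- rbind(c(0, 0), c(0, 10))
  expect_warning(wf <- build_weights(far, cutoff_deg = 5), "no neighbour")
  expect_true(all(wf$W == 0))
  expect_equal(wf$isolates, 1:2)
  expect_error(build_weights(rbind(c(0, 0), c(0, 0)), 5), "coincident")

  set.seed(61)
  coords <- cbind(runif(50, -30, 30), runif(50, -30, 30))
  w50 <- suppressWarnings(build_weights(coords, cutoff_deg = 8,
                                        row_standardize = FALSE))
  expect_equal(w50$W, oracle_weights(coords, 8), tolerance = 1e-10,
               ignore_attr = TRUE)
  # row-standardised rows sum to one
  wr <- suppressWarnings(build_weights(coords, cutoff_deg = 8))
  rs <- rowSums(wr$W)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
})

test_that("OLS baseline reproduces closed-form and limiting fits", {
  x <- c(0, 1, 2)
  y <- c(1, 3, 4) # closed form slope 1.5, intercept 7/6... check via formula
  f <- suppressWarnings(fit_ols(cbind(x = c(0, 1, 2, 3)), c(1, 3, 5, 7)))
  expect_equal(f$coefficients["x", "Estimate"], 2)
  expect_equal(f$r2, 1)
  f3 <- fit_ols(cbind(x = x), y)
  expect_equal(f3$coefficients["x", "Estimate"],
               sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2))
  set.seed(13)
  noise <- fit_ols(cbind(x = rnorm(500)), rnorm(500))
  expect_lt(abs(noise$adj_r2), 0.03)
  expect_error(fit_ols(cbind(a = 1:5, b = 2 * (1:5)), rnorm(5)),
               "rank-deficient|parameters")
})

test_that("spatial-error ML reduces to OLS when lambda is pinned at zero", {
  set.seed(67)
  coords <- cbind(runif(60, 0, 10), runif(60, 0, 10))
  w <- suppressWarnings(build_weights(coords, cutoff_deg = 3))
  X <- cbind(x1 = rnorm(60), x2 = runif(60))
  y <- 1 + 0.5 * X[, 1] - 0.3 * X[, 2] + rnorm(60, 0, 0.4)
  pinned <- fit_sar_error(X, y, w, interval = c(-1e-10, 1e-10))
  ols <- stats::lm(y ~ X)
  expect_equal(unname(pinned$coefficients$Estimate),
               unname(stats::coef(ols)), tolerance = 1e-8)
})

test_that("the profile log-likelihood is maximised at the returned lambda", {
  set.seed(73)
  coords <- as.matrix(expand.grid(lon = 1:8, lat = 1:8))
  w <- build_weights(coords, cutoff_deg = 1.5)
  X <- cbind(x = rnorm(64))
  y <- sim_sar_data(X, c(1, 0.5), 0.5, w$W, sigma = 0.5)
  fit <- fit_sar_error(X, y, w)
  grid_ll <- vapply(seq(-0.9, 0.9, length.out = 21), fit$profile, numeric(1))
  expect_true(all(fit$logLik >= grid_ll - 1e-8))
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$logLik)
})

test_that("ML estimates agree with a direct joint-optimisation oracle", {
  set.seed(79)
  for (i in 1:2) {
    coords <- as.matrix(expand.grid(lon = 1:7, lat = 1:7))
    w <- build_weights(coords, cutoff_deg = 1.5)
    X <- cbind(x = rnorm(49))
    y <- sim_sar_data(X, c(1, 0.5), 0.4, w$W, sigma = 0.6)
    fit <- fit_sar_error(X, y, w)
    ora <- oracle_sar_ml(X, y, w$W)
    expect_equal(unname(fit$coefficients$Estimate), unname(ora$beta),
                 tolerance = 1e-4)
    expect_equal(fit$lambda, unname(ora$lambda), tolerance = 1e-3)
    expect_equal(fit$logLik, ora$logLik, tolerance = 1e-3)
  }
})

test_that("Nagelkerke pseudo-R2 honours its identities and worked case", {
  expect_equal(nagelkerke_r2(-150, -150, n = 100), 0)
  # hand-evaluated: n = 100, L0 = -150, L1 = -120
  expect_equal(nagelkerke_r2(-120, -150, n = 100),
               (1 - exp(-0.6)) / (1 - exp(-3)), tolerance = 1e-12)
  # approaches 1 as the fitted likelihood dominates
  expect_gt(nagelkerke_r2(-1, -150, n = 100), 0.95)
  expect_warning(nagelkerke_r2(-151, -150, n = 100), "below null")
})

test_that("AIC-based cutoff selection returns a consistent table", {
  set.seed(97)
  coords <- as.matrix(expand.grid(lon = seq(0, 35, 5), lat = seq(0, 35, 5)))
  w <- build_weights(coords, cutoff_deg = 10)
  X <- cbind(x = rnorm(64))
  y <- sim_sar_data(X, c(0, 1), 0.5, w$W)
  single <- select_cutoff(X, y, coords, cutoffs = 15)
  expect_equal(single$best_cutoff, 15)
  sel <- select_cutoff(X, y, coords, cutoffs = c(6, 10, 20, 40))
  ok <- !is.na(sel$table$aic)
  expect_equal(sel$table$aic[ok], 2 * 4 - 2 * sel$table$logLik[ok])
  expect_equal(sel$best_cutoff, sel$table$cutoff[which.min(sel$table$aic)])
})
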