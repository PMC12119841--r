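# Independent brute-force oracles used to check the package implementations.
# Each one re-derives its quantity by a different algorithmic route (explicit
# path walks, nested-loop stencils, direct joint ML) so agreement is a real
# two-route check, not a tautology.

# equal-splits by explicit tip-to-root path walk
oracle_es <- function(tree, tip_idx) {
  w <- 1; es <- 0; node <- tip_idx
  repeat {
    i <- which(tree$edge[, 2] == node)
    if (length(i) == 0) break
    es <- es + tree$edge.length[i] * w
    parent <- tree$edge[i, 1]
    w <- w / sum(tree$edge[, 1] == parent)
    node <- parent
  }
  es
}

oracle_dr <- function(tree) {
  vapply(seq_len(ape::Ntip(tree)), function(i) 1 / oracle_es(tree, i),
         numeric(1))
}

# 3x3 max-min roughness by nested loops over available neighbours
oracle_roughness <- function(r) {
  n <- nrow(r); m <- ncol(r)
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    ri <- max(1, i - 1):min(n, i + 1)
    rj <- max(1, j - 1):min(m, j + 1)
    out[i, j] <- max(r[ri, rj]) - min(r[ri, rj])
  }
  out
}

# Horn slope magnitude by nested loops on a linearly extrapolated border
oracle_slope <- function(r, cell_km) {
  n <- nrow(r); m <- ncol(r)
  p <- matrix(NA_real_, n + 2, m + 2)
  p[2:(n + 1), 2:(m + 1)] <- r
  p[1, 2:(m + 1)] <- 2 * r[1, ] - r[2, ]
  p[n + 2, 2:(m + 1)] <- 2 * r[n, ] - r[n - 1, ]
  p[, 1] <- 2 * p[, 2] - p[, 3]
  p[, m + 2] <- 2 * p[, m + 1] - p[, m]
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    a <- i; b <- j # top-left corner of the 3x3 window in the padded matrix
    win <- p[a:(a + 2), b:(b + 2)]
    dzdx <- ((win[1, 3] + 2 * win[2, 3] + win[3, 3]) -
             (win[1, 1] + 2 * win[2, 1] + win[3, 1])) / (8 * cell_km)
    dzdy <- ((win[3, 1] + 2 * win[3, 2] + win[3, 3]) -
             (win[1, 1] + 2 * win[1, 2] + win[1, 3])) / (8 * cell_km)
    out[i, j] <- sqrt(dzdx^2 + dzdy^2)
  }
  out
}

oracle_velocity <- function(current, past, dt_years, cell_km) {
  sp <- oracle_slope(current, cell_km)
  v <- (abs(current - past) / dt_years) / sp
  v[sp == 0] <- NA_real_
  v
}

# inverse-power distance-band weights by explicit double loop (haversine)
oracle_weights <- function(coords, cutoff, power = 2) {
  n <- nrow(coords)
  hav <- function(p, q) {
    rad <- pi / 180
    dlat <- (q[2] - p[2]) * rad; dlon <- (q[1] - p[1]) * rad
    h <- sin(dlat / 2)^2 + cos(p[2] * rad) * cos(q[2] * rad) * sin(dlon / 2)^2
    2 * asin(sqrt(min(max(h, 0), 1))) / rad
  }
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- hav(coords[i, ], coords[j, ])
    if (d <= cutoff) W[i, j] <- 1 / d^power
  }
  W
}

# spatial-error ML by direct joint optimisation of the full log-likelihood
# over (beta, lambda): no profiling, log-determinant by dense LU
oracle_sar_ml <- function(X, y, W, lambda_bounds = c(-0.999, 0.999)) {
  Xd <- cbind(1, X)
  n <- length(y)
  negll <- function(par) {
    beta <- par[seq_len(ncol(Xd))]
    lambda <- par[length(par)]
    if (lambda <= lambda_bounds[1] || lambda >= lambda_bounds[2]) return(1e10)
    A <- diag(n) - lambda * W
    ld <- determinant(A, logarithm = TRUE)
    if (ld$sign <= 0) return(1e10)
    e <- A %*% (y - Xd %*% beta)
    s2 <- sum(e^2) / n
    -(-n / 2 * (log(2 * pi * s2) + 1) + as.numeric(ld$modulus))
  }
  start <- c(stats::coef(stats::lm.fit(Xd, y)), 0)
  opt <- stats::optim(start, negll, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
  opt <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
  list(beta = opt$par[seq_len(ncol(Xd))], lambda = opt$par[length(opt$par)],
       logLik = -opt$value)
}

# simulate from the spatial-error DGP y = Xb + (I - lambda W)^-1 eps
sim_sar_data <- function(X, beta, lambda, W, sigma = 1) {
  n <- nrow(W)
  eps <- stats::rnorm(n, 0, sigma)
  u <- solve(diag(n) - lambda * W, eps)
  as.vector(cbind(1, X) %*% beta + u)
}

# small fixed trees used across files
toy_tree <- function(txt) ape::read.tree(text = txt)
tree_pair <- function() toy_tree("(A:1,B:1);")
tree_balanced4 <- function() toy_tree("((A:1,B:1):1,(C:1,D:1):1);")
tree_caterpillar <- function() toy_tree("(((A:1,B:1):1,C:2):1,D:3);")

# random non-contiguous ranges: each species occupies a Bernoulli draw of
# cells (used where spatial contiguity must not correlate with the tree)
random_ranges <- function(species, grid, p_occ = 0.1) {
  out <- lapply(species, function(s) {
    cells <- which(stats::runif(grid$n_cells) < p_occ)
    if (length(cells) == 0) cells <- sample.int(grid$n_cells, 1)
    cells
  })
  names(out) <- species
  out
}
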