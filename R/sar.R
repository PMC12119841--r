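#' Distance-band inverse-power spatial weights
#'
#' Builds the neighbourhood weight matrix for spatial regressions: sites
#' within `cutoff_deg` great-circle degrees of each other are neighbours
#' with weight `1/d^power` (inverse squared distance by default); all other
#' pairs, and the diagonal, are zero. Row standardisation (each row scaled
#' to sum 1, the ecology-standard "W" style) is on by default; sites with no
#' neighbour inside the cutoff keep an all-zero row and are flagged.
#'
#' @param coords Two-column matrix or data.frame of site longitude, latitude
#'   in decimal degrees.
#' @param cutoff_deg Maximum connectivity distance in great-circle degrees.
#' @param power Exponent of the inverse-distance weight (default 2).
#' @param row_standardize Logical; divide each row by its sum (default TRUE).
#' @return An object of class `spatial_weights`: `W` (n x n), `coords`,
#'   `cutoff`, `power`, `row_standardized`, `isolates` (indices), and for
#'   row-standardised weights the symmetric base matrix `S` and row sums
#'   `d`, used for fast real-eigenvalue computation.
#' @export
build_weights <- function(coords, cutoff_deg, power = 2, row_standardize = TRUE) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2 || nrow(coords) < 2) stop("need >= 2 sites with (lon, lat)")
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  d <- gc_distance_deg(coords)
  dup <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
  if (nrow(dup) > 0) {
    stop("coincident sites (zero distance): pair ", dup[1, 1], " and ", dup[1, 2])
  }
  S <- ifelse(d > 0 & d <= cutoff_deg, 1 / d^power, 0)
  diag(S) <- 0
  rs <- rowSums(S)
  isolates <- which(rs == 0)
  if (length(isolates) > 0) {
    warning(length(isolates), " site(s) have no neighbour within ",
            cutoff_deg, " degrees; rows left zero")
  }
  W <- S
  if (row_standardize) {
    nz <- rs > 0
    W[nz, ] <- S[nz, , drop = FALSE] / rs[nz]
  }
  structure(list(W = W, coords = coords, cutoff = cutoff_deg, power = power,
                 row_standardized = row_standardize, isolates = isolates,
                 S = S, d = rs),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d sites, cutoff %g deg, 1/d^%g, %s, %d isolates\n",
              nrow(x$W), x$cutoff, x$power,
              if (x$row_standardized) "row-standardized" else "raw",
              length(x$isolates)))
  invisible(x)
}

#' Eigenvalues of a spatial weight matrix
#'
#' Computes the eigenvalues used in the spatial-error log-determinant.
#' A row-standardised W built from a symmetric base S is similar to
#' `D^(-1/2) S D^(-1/2)`, so its eigenvalues are real and computed with the
#' symmetric solver; otherwise the general (possibly complex) solver is
#' used. Precompute once and pass to [fit_sar_error()] via `ev` when fitting
#' many models on the same weights.
#'
#' @param w A `spatial_weights` object or bare matrix.
#' @return Numeric (or complex) vector of eigenvalues.
#' @export
weights_eigenvalues <- function(w) {
  W <- if (inherits(w, "spatial_weights")) w$W else as.matrix(w)
  if (inherits(w, "spatial_weights") && w$row_standardized &&
      !is.null(w$S) && length(w$isolates) == 0) {
    ds <- 1 / sqrt(w$d)
    M <- w$S * tcrossprod(ds)
    return(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  }
  if (isSymmetric(W, tol = 1e-12)) {
    return(eigen(W, symmetric = TRUE, only.values = TRUE)$values)
  }
  eigen(W, only.values = TRUE)$values
}

#' Ordinary least squares baseline fit
#'
#' Standard least-squares regression used as the non-spatial baseline; the
#' adjusted R-squared is the variance explained by the predictors alone,
#' reported next to the spatial model's pseudo-R-squared.
#'
#' @param X Numeric matrix or data.frame of predictors (no intercept
#'   column; one is added).
#' @param y Numeric response.
#' @return A list of class `ols_fit`: `coefficients` (data.frame with
#'   Estimate, Std.Error, t, p), `r2`, `adj_r2`, `logLik`, `aic`, `n`,
#'   `residuals`, `lm` (the underlying `lm` object).
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  if (nrow(X) <= ncol(X) + 1) stop("need n > number of parameters")
  dat <- data.frame(y = y, X, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = dat)
  if (anyNA(stats::coef(fit))) stop("rank-deficient design matrix")
  sm <- summary(fit)
  coefs <- as.data.frame(sm$coefficients)
  names(coefs) <- c("Estimate", "Std.Error", "t", "p")
  structure(list(coefficients = coefs, r2 = sm$r.squared,
                 adj_r2 = sm$adj.r.squared,
                 logLik = as.numeric(stats::logLik(fit)),
                 aic = stats::AIC(fit), n = length(y),
                 residuals = stats::residuals(fit), lm = fit),
            class = "ols_fit")
}

#' Maximum-likelihood spatial-error regression
#'
#' Fits `y = X beta + u`, `u = lambda W u + eps`, `eps ~ iid N(0, sigma2)`
#' by profile maximum likelihood: for each candidate spatial coefficient
#' `lambda`, `beta` and `sigma2` have closed-form GLS solutions on the
#' transformed system `(I - lambda W) y = (I - lambda W) X beta + eps`, and
#' the concentrated log-likelihood
#' `const - n/2 log sigma2(lambda) + log|I - lambda W|`
#' is maximised over the stationarity interval with the log-determinant
#' evaluated from the (precomputable) eigenvalues of W. Coefficient
#' standard errors are the GLS covariance conditional on the fitted lambda;
#' the lambda standard error comes from the curvature of the profile
#' log-likelihood.
#'
#' @param X Predictor matrix/data.frame (intercept added internally).
#' @param y Numeric response.
#' @param w A `spatial_weights` object (or bare matrix) over the same sites.
#' @param ev Optional precomputed eigenvalues of W (reuse across fits on
#'   the same weights).
#' @param interval Optional lambda search interval; defaults to the
#'   stationarity interval from the eigenvalues intersected with (-1, 1).
#' @return An object of class `sar_error_fit`: `coefficients` (Estimate,
#'   Std.Error, z, p), `lambda`, `lambda_se`, `sigma2`, `logLik`, `aic`,
#'   `n`, `k`, `residuals` (spatially filtered), `profile` (function
#'   lambda -> profile log-likelihood), `interval`.
#' @export
fit_sar_error <- function(X, y, w, ev = NULL, interval = NULL) {
  X <- as.matrix(X)
  if (ncol(X) > 0 && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  W <- if (inherits(w, "spatial_weights")) w$W else as.matrix(w)
  n <- length(y)
  if (nrow(X) != n || nrow(W) != n) stop("X, y and W sizes differ")
  if (any(!is.finite(y))) stop("non-finite response")
  Xd <- cbind(`(Intercept)` = 1, X)
  if (qr(Xd)$rank < ncol(Xd)) stop("rank-deficient design matrix")
  if (is.null(ev)) ev <- weights_eigenvalues(w)
  re <- Re(ev)
  if (is.null(interval)) {
    lo <- if (min(re) < 0) 1 / min(re) else -Inf
    hi <- if (max(re) > 0) 1 / max(re) else Inf
    eps <- 1e-6
    interval <- c(max(lo + eps, -1 + eps), min(hi - eps, 1 - eps))
  }
  if (interval[1] >= interval[2]) stop("empty lambda interval: [",
                                       interval[1], ", ", interval[2], "]")
  Wy <- W %*% y
  WX <- W %*% Xd
  logdet <- function(lambda) sum(log(Mod(1 - lambda * ev)))
  profile_fit <- function(lambda) {
    Ay <- y - lambda * Wy
    AX <- Xd - lambda * WX
    fit <- stats::lm.fit(AX, Ay)
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / n
    ll <- -n / 2 * (log(2 * pi * sigma2) + 1) + logdet(lambda)
    list(ll = ll, beta = fit$coefficients, sigma2 = sigma2,
         AX = AX, resid = fit$residuals)
  }
  profile <- function(lambda) profile_fit(lambda)$ll
  opt <- stats::optimize(profile, interval = interval, maximum = TRUE,
                         tol = 1e-9)
  lambda_hat <- opt$maximum
  at <- profile_fit(lambda_hat)
  if (!all(is.finite(at$beta))) {
    stop("non-convergence: non-finite coefficients at lambda = ", lambda_hat,
         " (interval [", interval[1], ", ", interval[2], "])")
  }
  # conditional-on-lambda covariance of beta
  xtx_inv <- chol2inv(chol(crossprod(at$AX)))
  se <- sqrt(at$sigma2 * diag(xtx_inv))
  z <- at$beta / se
  p <- 2 * stats::pnorm(-abs(z))
  coefs <- data.frame(Estimate = at$beta, Std.Error = se, z = z, p = p,
                      row.names = colnames(Xd))
  # profile curvature -> lambda standard error
  h <- min(1e-4, (interval[2] - interval[1]) / 100,
           lambda_hat - interval[1], interval[2] - lambda_hat) / 2
  lambda_se <- NA_real_
  if (h > 0) {
    d2 <- (profile(lambda_hat + h) - 2 * opt$objective + profile(lambda_hat - h)) / h^2
    if (is.finite(d2) && d2 < 0) lambda_se <- sqrt(-1 / d2)
  }
  k <- ncol(Xd) + 2 # beta (incl. intercept), lambda, sigma2
  structure(list(coefficients = coefs, lambda = lambda_hat,
                 lambda_se = lambda_se, sigma2 = at$sigma2,
                 logLik = opt$objective, aic = 2 * k - 2 * opt$objective,
                 n = n, k = k, residuals = at$resid,
                 profile = profile, interval = interval),
            class = "sar_error_fit")
}

#' @export
print.sar_error_fit <- function(x, ...) {
  cat(sprintf("spatial-error ML fit: n = %d, lambda = %.4f, logLik = %.3f, AIC = %.2f\n",
              x$n, x$lambda, x$logLik, x$aic))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Nagelkerke pseudo-R-squared
#'
#' Likelihood-ratio fit measure normalised to its attainable maximum:
#' `R2 = (1 - exp((2/n)(L0 - L1))) / (1 - exp((2/n) L0))`, where `L1` and
#' `L0` are the log-likelihoods of the fitted model and of the intercept-only
#' null of the same family. Equals 0 when the model adds nothing and
#' approaches 1 in the perfect-fit limit. The denominator assumes the null
#' likelihood is at most 1; when a continuous model has positive `L0` the
#' normaliser is non-positive and the raw Cox-Snell ratio is returned
#' instead (clamped to `[0, 1]`).
#'
#' @param fit,null_fit Fitted models carrying `logLik` and `n` (e.g.
#'   `sar_error_fit`s), or bare numeric log-likelihoods (then supply `n`).
#' @param n Number of observations; required when log-likelihoods are given
#'   as bare numbers.
#' @return Scalar in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit, null_fit, n = NULL) {
  l1 <- if (is.numeric(fit)) fit else fit$logLik
  l0 <- if (is.numeric(null_fit)) null_fit else null_fit$logLik
  if (is.null(n)) {
    n <- if (is.numeric(fit)) stop("supply n with bare log-likelihoods") else fit$n
    if (!is.numeric(null_fit) && null_fit$n != n) stop("fits have different n")
  }
  if (l1 < l0 - 1e-8) {
    warning("fitted log-likelihood below null (optimizer issue?); truncating at 0")
  }
  cox_snell <- 1 - exp((2 / n) * (l0 - l1))
  max_cs <- 1 - exp((2 / n) * l0)
  # the Nagelkerke maximum assumes likelihood <= 1; for continuous densities
  # a positive null log-likelihood makes it non-positive, in which case the
  # raw Cox-Snell ratio is reported unnormalised
  r2 <- if (max_cs > 0) cox_snell / max_cs else cox_snell
  max(0, min(1, r2))
}

#' Select the neighbourhood cutoff by AIC
#'
#' Fits the spatial-error model over a ladder of maximum connectivity
#' distances and returns the cutoff with the lowest AIC, together with the
#' full table. Per-cutoff failures are recorded rather than fatal.
#'
#' @param X Predictor matrix/data.frame.
#' @param y Numeric response.
#' @param coords Site (lon, lat) matrix.
#' @param cutoffs Numeric vector of candidate cutoffs in degrees (>= 1
#'   candidate).
#' @param power,row_standardize Passed to [build_weights()].
#' @return A list: `best_cutoff`, `best_fit`, `table` (cutoff, aic, logLik,
#'   lambda, error message if failed).
#' @export
select_cutoff <- function(X, y, coords, cutoffs = seq(10, 100, by = 10),
                          power = 2, row_standardize = TRUE) {
  if (length(cutoffs) < 1) stop("no candidate cutoffs")
  rows <- vector("list", length(cutoffs))
  fits <- vector("list", length(cutoffs))
  for (i in seq_along(cutoffs)) {
    res <- tryCatch({
      w <- suppressWarnings(build_weights(coords, cutoffs[i], power = power,
                                          row_standardize = row_standardize))
      fit <- fit_sar_error(X, y, w)
      fits[[i]] <- fit
      data.frame(cutoff = cutoffs[i], aic = fit$aic, logLik = fit$logLik,
                 lambda = fit$lambda, error = NA_character_)
    }, error = function(e) {
      data.frame(cutoff = cutoffs[i], aic = NA_real_, logLik = NA_real_,
                 lambda = NA_real_, error = conditionMessage(e))
    })
    rows[[i]] <- res
  }
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$aic))) stop("all cutoffs failed; first error: ", tab$error[1])
  best <- which.min(tab$aic)
  list(best_cutoff = cutoffs[best], best_fit = fits[[best]], table = tab)
}
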