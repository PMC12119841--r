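#' Per-state tip speciation rate estimates
#'
#' Estimates the speciation rate of each binary trait state as the
#' arithmetic mean of the inverse equal-splits tip statistic over the tips
#' currently in that state. This is the branch-length-based, model-free
#' rate summary underlying the state-dependent test.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param traits Named 0/1 vector over all tips of `tree`.
#' @return Named numeric vector `c(lambda0, lambda1)`.
#' @export
state_lambda <- function(tree, traits) {
  traits <- check_traits(tree, traits)
  dr <- dr_statistic(tree)
  c(lambda0 = mean(dr[names(traits)[traits == 0L]]),
    lambda1 = mean(dr[names(traits)[traits == 1L]]))
}

check_traits <- function(tree, traits) {
  if (is.null(names(traits))) stop("traits must be a named vector")
  miss <- setdiff(tree$tip.label, names(traits))
  if (length(miss) > 0) {
    stop("traits missing for tips: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  traits <- traits[tree$tip.label]
  if (!all(traits %in% c(0, 1))) stop("traits must be coded 0/1")
  traits <- as.integer(traits)
  names(traits) <- tree$tip.label
  if (length(unique(traits)) < 2L) stop("single state: test undefined")
  traits
}

#' Fitch parsimony count of binary state changes on a tree
#'
#' Minimum number of 0/1 state changes required to explain the tip states,
#' by the standard Fitch bottom-up pass (generalised to polytomies: a union
#' at a node counts one change).
#'
#' @param tree A rooted `phylo`.
#' @param traits Named 0/1 vector over tips.
#' @return Non-negative integer change count.
#' @export
fitch_changes <- function(tree, traits) {
  traits <- traits[tree$tip.label]
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  # state sets encoded as bitmasks: 1 = {0}, 2 = {1}, 3 = {0,1}
  setm <- integer(ntip + nnode)
  setm[seq_len(ntip)] <- ifelse(traits == 0L, 1L, 2L)
  changes <- 0L
  po <- ape::reorder.phylo(tree, "postorder")
  e1 <- po$edge[, 1]; e2 <- po$edge[, 2]
  for (node in unique(e1)) {
    kids <- e2[e1 == node]
    inter <- Reduce(bitwAnd, setm[kids])
    if (inter > 0L) {
      setm[node] <- inter
    } else {
      setm[node] <- Reduce(bitwOr, setm[kids])
      changes <- changes + 1L
    }
  }
  changes
}

#' Simulate null trait sets by neutral character evolution on the tree
#'
#' Generates trait sets under a symmetric two-state Markov (Mk) model evolved
#' along the tree, the model-free null of the state-dependent test. The
#' transition rate is calibrated from the data: the Fitch parsimony estimate
#' of the number of observed state changes divided by the total tree length
#' (with a floor of 1/tree_length when the observed trait needs no changes).
#' The root state of each replicate is drawn from the observed state
#' frequencies. Replicates that come out monomorphic are resampled (the
#' state-dependent statistic is undefined for them); resampling is capped
#' and reported.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param traits Named 0/1 vector over tips (the observed trait).
#' @param n_null Number of null trait sets (>= 100 for inference; smaller
#'   values allowed for mechanics).
#' @param seed Optional integer seed.
#' @param max_resample Cap on monomorphic-replicate resampling rounds.
#' @return Integer matrix, tips x `n_null`, rownames = tip labels;
#'   `attr(,"q")` records the calibrated rate.
#' @export
simulate_null_traits <- function(tree, traits, n_null, seed = NULL,
                                 max_resample = 100) {
  traits <- check_traits(tree, traits)
  if (!is.null(seed)) set.seed(seed)
  total_len <- sum(tree$edge.length)
  if (total_len <= 0) stop("tree has zero total length")
  changes <- fitch_changes(tree, traits)
  q <- if (changes > 0L) changes / total_len else 1 / total_len
  p1 <- mean(traits == 1L)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  tr <- ape::reorder.phylo(tree, "cladewise")
  e1 <- tr$edge[, 1]; e2 <- tr$edge[, 2]
  # exact endpoint flip probability of a symmetric 2-state chain over length t
  pflip <- (1 - exp(-2 * q * tr$edge.length)) / 2
  draw <- function(m) {
    st <- matrix(0L, ntip + tree$Nnode, m)
    st[root, ] <- stats::rbinom(m, 1L, p1)
    for (i in seq_along(e1)) {
      flip <- stats::rbinom(m, 1L, pflip[i])
      st[e2[i], ] <- bitwXor(st[e1[i], ], flip)
    }
    st[seq_len(ntip), , drop = FALSE]
  }
  out <- draw(n_null)
  for (round in seq_len(max_resample)) {
    mono <- which(colSums(out) %in% c(0L, ntip))
    if (length(mono) == 0L) break
    out[, mono] <- draw(length(mono))
  }
  mono <- colSums(out) %in% c(0L, ntip)
  if (any(mono)) {
    stop("could not obtain polymorphic null traits after ", max_resample,
         " resampling rounds (q too small?)")
  }
  rownames(out) <- tr$tip.label
  out <- out[tree$tip.label, , drop = FALSE]
  attr(out, "q") <- q
  out
}

#' Nonparametric test for binary state-dependent speciation (one tree)
#'
#' Compares the observed difference in per-state mean tip rate,
#' `delta = lambda1 - lambda0`, against its distribution over neutral-trait
#' simulations on the same tree ([simulate_null_traits()]). The one-tailed
#' proportion `p1 = (1 + #\{null >= observed\}) / (n_null + 1)` is doubled on
#' the smaller side and capped at 1 to give a two-tailed p-value; the +1
#' pseudocount keeps p positive.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param traits Named 0/1 vector over tips.
#' @param n_null Number of null simulations (default 1000).
#' @param seed Optional integer seed.
#' @return An object of class `fisse_result`: `lambda0`, `lambda1`,
#'   `delta_obs`, `null_deltas`, `p_value`, `n_null`, `seed`.
#' @export
fisse_pvalue <- function(tree, traits, n_null = 1000, seed = NULL) {
  traits <- check_traits(tree, traits)
  dr <- dr_statistic(tree)
  lam <- state_lambda(tree, traits)
  delta_obs <- unname(lam["lambda1"] - lam["lambda0"])
  nulls <- simulate_null_traits(tree, traits, n_null, seed = seed)
  n1 <- colSums(nulls)
  sum1 <- as.vector(crossprod(nulls, dr[rownames(nulls)]))
  sum_all <- sum(dr)
  null_deltas <- sum1 / n1 - (sum_all - sum1) / (length(dr) - n1)
  p1 <- (1 + sum(null_deltas >= delta_obs)) / (n_null + 1)
  p <- min(1, 2 * min(p1, 1 - p1))
  structure(list(lambda0 = unname(lam["lambda0"]),
                 lambda1 = unname(lam["lambda1"]),
                 delta_obs = delta_obs, null_deltas = null_deltas,
                 p_value = p, n_null = n_null, seed = seed),
            class = "fisse_result")
}

#' @export
print.fisse_result <- function(x, ...) {
  cat(sprintf("state-dependent tip-rate test: lambda0 = %.4g, lambda1 = %.4g, delta = %.4g, p = %.4g (n_null = %d)\n",
              x$lambda0, x$lambda1, x$delta_obs, x$p_value, x$n_null))
  invisible(x)
}

#' Batch state-dependent test over a posterior sample of trees
#'
#' Runs [fisse_pvalue()] on each tree of a posterior sample (shared tip set)
#' and summarises the across-tree mean per-state rates -- the quantity
#' reported when rate differences are averaged over tree uncertainty.
#'
#' @param trees List of `phylo` objects sharing one tip set.
#' @param traits Named 0/1 vector over the shared tips.
#' @param n_null Null simulations per tree.
#' @param seed Optional integer seed; per-tree seeds are derived from it.
#' @return A list: `results` (per-tree `fisse_result`s), `mean_lambda0`,
#'   `mean_lambda1`, `mean_delta`, `mean_p`, `per_tree` (data.frame).
#' @export
fisse_batch <- function(trees, traits, n_null = 1000, seed = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref)) {
      stop("tree ", i, " does not share the common tip set")
    }
  }
  seeds <- if (is.null(seed)) rep(list(NULL), length(trees)) else
    as.list(seed + seq_along(trees) - 1L)
  results <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    results[[i]] <- fisse_pvalue(trees[[i]], traits, n_null = n_null,
                                 seed = seeds[[i]])
  }
  per_tree <- data.frame(
    tree = seq_along(results),
    lambda0 = vapply(results, `[[`, numeric(1), "lambda0"),
    lambda1 = vapply(results, `[[`, numeric(1), "lambda1"),
    delta = vapply(results, `[[`, numeric(1), "delta_obs"),
    p_value = vapply(results, `[[`, numeric(1), "p_value")
  )
  list(results = results,
       mean_lambda0 = mean(per_tree$lambda0),
       mean_lambda1 = mean(per_tree$lambda1),
       mean_delta = mean(per_tree$delta),
       mean_p = mean(per_tree$p_value),
       per_tree = per_tree)
}
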