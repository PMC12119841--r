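#' Simulate a time-calibrated birth-death tree conditioned on tip count
#'
#' Forward (Gillespie) simulation of a constant-rate birth-death process
#' started from two crown lineages, stopped the first time the number of
#' extant lineages reaches `n_tips`. The present is then placed a random
#' waiting time before the next event (drawn from the process itself), so
#' terminal branches have positive length, and extinct subtrees are pruned.
#' The returned tree is ultrametric with exactly `n_tips` extant tips.
#'
#' @param lambda Speciation rate (> 0), events per time unit.
#' @param mu Extinction rate (>= 0, < lambda).
#' @param n_tips Number of extant tips to condition on (>= 2).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param max_retries Maximum restarts after total extinction.
#' @param tip_prefix Prefix for tip labels (`t1`, `t2`, ... by default).
#' @return A `phylo` object.
#' @export
simulate_bd_tree <- function(lambda, mu = 0, n_tips, seed = NULL,
                             max_retries = 1000, tip_prefix = "t") {
  res <- simulate_bisse_tree(lambda0 = lambda, lambda1 = lambda, q = 0,
                             mu = mu, n_tips = n_tips, seed = seed,
                             max_retries = max_retries, tip_prefix = tip_prefix)
  res$tree
}

#' Simulate a binary-state-dependent (BiSSE-style) tree and tip states
#'
#' Forward character-and-tree simulation: a lineage in state k speciates at
#' rate `lambdak`, goes extinct at rate `mu`, and flips state at rate `q`
#' (symmetric). Daughters inherit the parent state at speciation. Stopping
#' and pruning as in [simulate_bd_tree()]; with `lambda0 == lambda1` the
#' process reduces to a plain birth-death tree plus a neutral trait.
#'
#' @param lambda0,lambda1 Speciation rates in states 0 and 1 (> 0).
#' @param q Symmetric state transition rate (>= 0).
#' @param mu Extinction rate (>= 0).
#' @param n_tips Number of extant tips (>= 2).
#' @param root_state State of the two crown lineages (0 or 1).
#' @param seed Optional integer seed.
#' @param max_retries Maximum restarts after total extinction.
#' @param tip_prefix Prefix for tip labels.
#' @return A list with `tree` (`phylo`) and `states` (named 0/1 integer
#'   vector over tips).
#' @export
simulate_bisse_tree <- function(lambda0, lambda1, q, n_tips, mu = 0,
                                root_state = 0L, seed = NULL,
                                max_retries = 1000, tip_prefix = "t") {
  stopifnot(lambda0 > 0, lambda1 > 0, q >= 0, mu >= 0, n_tips >= 2)
  if (mu >= min(lambda0, lambda1)) {
    stop("extinction rate must be below both speciation rates")
  }
  if (!is.null(seed)) set.seed(seed)
  lam <- c(lambda0, lambda1)
  for (attempt in seq_len(max_retries)) {
    sim <- bd_forward_once(lam, mu, q, n_tips, as.integer(root_state))
    if (!is.null(sim)) {
      nwk <- lineages_to_newick(sim, tip_prefix)
      tree <- ape::read.tree(text = nwk$newick)
      states <- stats::setNames(nwk$states[tree$tip.label], tree$tip.label)
      return(list(tree = tree, states = states))
    }
  }
  stop("birth-death simulation went extinct in all ", max_retries,
       " attempts; parameters not viable for n_tips = ", n_tips)
}

#' Simulate a birth-death tree of fixed crown age
#'
#' Forward simulation from two crown lineages over a fixed time span `age`;
#' the number of extant tips is random (roughly `2 exp(lambda * age)` for a
#' pure-birth process), so faster clades are richer but all clades are
#' equally deep. Used to plant rate differences across clades without
#' confounding them with clade depth. Simulations ending with fewer than
#' `min_tips` survivors are retried.
#'
#' @param lambda Speciation rate (> 0).
#' @param mu Extinction rate (>= 0).
#' @param age Crown age in time units (> 0).
#' @param min_tips Minimum surviving tips (default 2).
#' @param max_tips Safety cap; exceeding it aborts the attempt.
#' @param seed Optional integer seed.
#' @param max_retries Maximum restarts.
#' @param tip_prefix Prefix for tip labels.
#' @return A `phylo` object with crown age exactly `age`.
#' @export
simulate_bd_tree_age <- function(lambda, mu = 0, age, min_tips = 2,
                                 max_tips = 5000, seed = NULL,
                                 max_retries = 1000, tip_prefix = "t") {
  stopifnot(lambda > 0, mu >= 0, age > 0, min_tips >= 2)
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(max_retries)) {
    sim <- bd_forward_time(c(lambda, lambda), mu, 0, age, 0L, max_tips)
    if (!is.null(sim) && sum(sim$alive) >= min_tips) {
      nwk <- lineages_to_newick(sim, tip_prefix)
      return(ape::read.tree(text = nwk$newick))
    }
  }
  stop("no clade with >= ", min_tips, " tips after ", max_retries,
       " attempts (lambda = ", lambda, ", age = ", age, ")")
}

# Forward pass over a fixed time span. Returns NULL on total extinction or
# tip-count overflow; otherwise the lineage table at time `age`.
bd_forward_time <- function(lam, mu, q, age, root_state, max_tips = 5000) {
  cap <- 256L
  parent <- integer(cap); t_start <- numeric(cap); t_end <- numeric(cap)
  state <- integer(cap); alive <- logical(cap)
  parent[1:2] <- 0L; t_start[1:2] <- 0; state[1:2] <- root_state
  alive[1:2] <- TRUE
  n_lin <- 2L
  t <- 0
  repeat {
    idx <- which(alive[seq_len(n_lin)])
    n_alive <- length(idx)
    if (n_alive == 0L) return(NULL)
    if (n_alive > max_tips) return(NULL)
    rate_i <- lam[state[idx] + 1L] + mu + q
    dt <- stats::rexp(1L, sum(rate_i))
    if (t + dt >= age) {
      t_end[idx] <- age
      return(list(parent = parent[seq_len(n_lin)],
                  t_start = t_start[seq_len(n_lin)],
                  t_end = t_end[seq_len(n_lin)],
                  state = state[seq_len(n_lin)],
                  alive = alive[seq_len(n_lin)]))
    }
    t <- t + dt
    who <- idx[sample.int(n_alive, 1L, prob = rate_i)]
    u <- stats::runif(1L) * (lam[state[who] + 1L] + mu + q)
    if (u < lam[state[who] + 1L]) {
      if (n_lin + 2L > cap) {
        cap <- cap * 2L
        length(parent) <- cap; length(t_start) <- cap; length(t_end) <- cap
        length(state) <- cap; length(alive) <- cap
        parent[is.na(parent)] <- 0L
      }
      alive[who] <- FALSE; t_end[who] <- t
      for (k in 1:2) {
        n_lin <- n_lin + 1L
        parent[n_lin] <- who; t_start[n_lin] <- t
        state[n_lin] <- state[who]; alive[n_lin] <- TRUE
      }
    } else if (u < lam[state[who] + 1L] + mu) {
      alive[who] <- FALSE; t_end[who] <- t
    } else {
      state[who] <- 1L - state[who]
    }
  }
}

# One forward pass. Returns NULL on total extinction before reaching n_tips,
# otherwise a lineage table (parent, t_start, t_end, state, alive).
bd_forward_once <- function(lam, mu, q, n_tips, root_state) {
  cap <- max(4L * n_tips, 64L)
  parent <- integer(cap); t_start <- numeric(cap); t_end <- numeric(cap)
  state <- integer(cap); alive <- logical(cap)
  parent[1:2] <- 0L; t_start[1:2] <- 0; state[1:2] <- root_state
  alive[1:2] <- TRUE
  n_lin <- 2L
  t <- 0
  repeat {
    idx <- which(alive[seq_len(n_lin)])
    n_alive <- length(idx)
    if (n_alive == 0L) return(NULL)
    rate_i <- lam[state[idx] + 1L] + mu + q
    total <- sum(rate_i)
    dt <- stats::rexp(1L, total)
    if (n_alive == n_tips) {
      # stop just before the next event: present = t + dt
      t_end[idx] <- t + dt
      return(list(parent = parent[seq_len(n_lin)],
                  t_start = t_start[seq_len(n_lin)],
                  t_end = t_end[seq_len(n_lin)],
                  state = state[seq_len(n_lin)],
                  alive = alive[seq_len(n_lin)]))
    }
    t <- t + dt
    who <- idx[sample.int(n_alive, 1L, prob = rate_i)]
    u <- stats::runif(1L) * (lam[state[who] + 1L] + mu + q)
    if (u < lam[state[who] + 1L]) {       # speciation: two daughters
      if (n_lin + 2L > cap) {
        cap <- cap * 2L
        length(parent) <- cap; length(t_start) <- cap; length(t_end) <- cap
        length(state) <- cap; length(alive) <- cap
        parent[is.na(parent)] <- 0L
      }
      alive[who] <- FALSE; t_end[who] <- t
      for (k in 1:2) {
        n_lin <- n_lin + 1L
        parent[n_lin] <- who; t_start[n_lin] <- t
        state[n_lin] <- state[who]; alive[n_lin] <- TRUE
      }
    } else if (u < lam[state[who] + 1L] + mu) {  # extinction
      alive[who] <- FALSE; t_end[who] <- t
    } else {                               # state flip
      state[who] <- 1L - state[who]
    }
  }
}

# Prune extinct subtrees, collapse pass-through nodes, emit Newick.
lineages_to_newick <- function(sim, tip_prefix) {
  n <- length(sim$parent)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    p <- sim$parent[i]
    if (p > 0L) children[[p]] <- c(children[[p]], i)
  }
  # survivors: lineages with at least one extant descendant (or extant)
  surv <- logical(n)
  for (i in rev(seq_len(n))) { # children have larger indices than parents
    surv[i] <- sim$alive[i] ||
      (length(children[[i]]) > 0L && any(surv[children[[i]]]))
  }
  tip_counter <- 0L
  states <- integer(0)
  build <- function(i) {
    len <- sim$t_end[i] - sim$t_start[i]
    kids <- children[[i]]
    kids <- kids[surv[kids]]
    if (length(kids) == 0L) { # extant tip
      tip_counter <<- tip_counter + 1L
      lab <- paste0(tip_prefix, tip_counter)
      states[lab] <<- sim$state[i]
      return(list(str = lab, len = len))
    }
    if (length(kids) == 1L) { # pass-through: sister went extinct
      sub <- build(kids[1L])
      sub$len <- sub$len + len
      return(sub)
    }
    subs <- lapply(kids, build)
    parts <- vapply(subs, function(s) paste0(s$str, ":", format(s$len, digits = 15)),
                    character(1))
    list(str = paste0("(", paste(parts, collapse = ","), ")"), len = len)
  }
  roots <- which(sim$parent == 0L & surv)
  if (length(roots) == 2L) {
    a <- build(roots[1L]); b <- build(roots[2L])
    nwk <- paste0("(", a$str, ":", format(a$len, digits = 15), ",",
                  b$str, ":", format(b$len, digits = 15), ");")
  } else { # one crown lineage left: its first surviving split is the root
    a <- build(roots[1L])
    if (!startsWith(a$str, "(")) stop("degenerate simulation: single tip")
    nwk <- paste0(a$str, ";")
  }
  list(newick = nwk, states = states)
}

#' Emulate a posterior sample by jittering branch lengths
#'
#' Produces `n` copies of `tree` whose branch lengths are multiplied by
#' independent lognormal noise (median 1). This mimics the branch-length
#' (not topological) component of posterior uncertainty: all trees share
#' the tip set and topology, and tip depths wobble mildly around the
#' original tree's.
#'
#' @param tree A `phylo`.
#' @param n Number of posterior draws.
#' @param sdlog Lognormal standard deviation of the multiplicative jitter.
#' @param seed Optional integer seed.
#' @return A list of `phylo` objects (first element is `tree` itself).
#' @export
jitter_posterior <- function(tree, n, sdlog = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n)
  out[[1]] <- tree
  if (n == 1) return(out)
  for (i in 2:n) {
    tr <- tree
    tr$edge.length <- tr$edge.length *
      stats::rlnorm(length(tr$edge.length), 0, sdlog)
    out[[i]] <- tr
  }
  out
}
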