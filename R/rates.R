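#' Equal-splits statistic for one tip
#'
#' The equal-splits (ES) value of a tip is the sum, over the edges on its
#' root-to-tip path, of the edge length discounted by the splits passed on
#' the way down: the terminal edge counts in full, and the weight is divided
#' by the number of daughters at each successively deeper node. For a binary
#' tree this is \eqn{\sum_j \ell_j (1/2)^{j-1}} with \eqn{j = 1} at the tip.
#' At a polytomy with m daughters the factor generalises from 1/2 to 1/m,
#' preserving the interpretation of splitting the parent's "credit" equally
#' among daughters.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param tip Tip label (character) or tip index (integer).
#' @return A positive scalar, in the time units of the branch lengths.
#' @seealso [dr_statistic()] for all tips at once.
#' @export
equal_splits <- function(tree, tip) {
  validate_phylogeny(tree)
  if (is.character(tip)) {
    idx <- match(tip, tree$tip.label)
    if (is.na(idx)) stop("tip '", tip, "' not in tree")
  } else {
    idx <- as.integer(tip)
    if (idx < 1 || idx > ape::Ntip(tree)) stop("tip index out of range")
  }
  es <- unname(es_all_tips(tree)[idx])
  if (es <= 0) stop("degenerate tip path: zero total path length for tip '",
                    tree$tip.label[idx], "'")
  es
}

# ES for every tip in one preorder pass. Recurrence: with T(root) = 0,
# T(child) = T(parent) / n_daughters(parent) + edge_length; ES(tip) = T(tip).
es_all_tips <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise") # parents before children
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  nchild <- tabulate(tree$edge[, 1], nbins = ntip + nnode)
  acc <- numeric(ntip + nnode)
  e1 <- tree$edge[, 1]; e2 <- tree$edge[, 2]; len <- tree$edge.length
  for (i in seq_along(len)) {
    acc[e2[i]] <- acc[e1[i]] / nchild[e1[i]] + len[i]
  }
  stats::setNames(acc[seq_len(ntip)], tree$tip.label)
}

#' Tip speciation rates: the DR statistic (inverse equal-splits)
#'
#' Computes the diversification-rate (DR) tip statistic for every species in
#' the tree: the reciprocal of the equal-splits value. DR summarises the
#' number of splits and internode distances along the root-to-tip path,
#' weighting recent branches most, and behaves as a proxy for the
#' speciation rate at the tip (units: events per time unit).
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return Named numeric vector of rates, one per tip.
#' @export
dr_statistic <- function(tree) {
  validate_phylogeny(tree)
  term <- terminal_lengths(tree)
  if (any(term == 0)) {
    stop("zero-length terminal edge(s) for: ",
         paste(names(term)[term == 0], collapse = ", "),
         " (would give infinite DR)")
  }
  es <- es_all_tips(tree)
  if (any(es <= 0)) stop("degenerate tip path: zero total path length")
  1 / es
}

# terminal branch length per tip, named
terminal_lengths <- function(tree) {
  ntip <- ape::Ntip(tree)
  is_term <- tree$edge[, 2] <= ntip
  stats::setNames(tree$edge.length[is_term][order(tree$edge[is_term, 2])],
                  tree$tip.label)
}

#' Aggregate tip rates across a posterior sample of trees
#'
#' Computes per-species DR for each tree in a posterior sample and combines
#' them into one table. All trees must share an identical tip set (topology
#' and branch lengths may differ). Species age is operationalised as the
#' terminal branch length, averaged across trees.
#'
#' @param trees A list of `phylo` objects (or a `multiPhylo`).
#' @param mean_type How per-tree DR values are combined per species:
#'   `"arithmetic"` (default) or `"harmonic"`.
#' @return A `data.frame` of class `tip_rate_table` with columns `species`,
#'   `dr_mean`, `dr_sd`, `age`, plus the per-tree rates in
#'   `attr(, "dr_per_tree")` (species x trees matrix).
#' @export
aggregate_posterior <- function(trees, mean_type = c("arithmetic", "harmonic")) {
  mean_type <- match.arg(mean_type)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) < 1) stop("empty posterior sample")
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    lab <- sort(trees[[i]]$tip.label)
    if (!identical(lab, ref)) {
      extra <- setdiff(lab, ref); missing <- setdiff(ref, lab)
      stop("tree ", i, " tip set differs from tree 1; only in tree ", i, ": {",
           paste(extra, collapse = ","), "}; only in tree 1: {",
           paste(missing, collapse = ","), "}")
    }
  }
  dr <- vapply(trees, function(tr) dr_statistic(tr)[ref], numeric(length(ref)))
  age <- vapply(trees, function(tr) terminal_lengths(tr)[ref], numeric(length(ref)))
  dr <- matrix(dr, nrow = length(ref), dimnames = list(ref, NULL))
  age <- matrix(age, nrow = length(ref))
  dr_mean <- switch(mean_type,
    arithmetic = rowMeans(dr),
    harmonic   = 1 / rowMeans(1 / dr)
  )
  out <- data.frame(
    species = ref,
    dr_mean = unname(dr_mean),
    dr_sd = unname(apply(dr, 1, stats::sd)),
    age = unname(rowMeans(age)),
    stringsAsFactors = FALSE
  )
  attr(out, "dr_per_tree") <- dr
  attr(out, "mean_type") <- mean_type
  class(out) <- c("tip_rate_table", "data.frame")
  out
}

#' Write / read a tip-rate table as CSV
#'
#' @param table A `tip_rate_table` from [aggregate_posterior()].
#' @param path CSV path with columns species, dr_mean, dr_sd, age.
#' @return `path` (write) or a `tip_rate_table` (read).
#' @export
write_tip_rates <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("species", "dr_mean", "dr_sd", "age")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tip_rates
#' @export
read_tip_rates <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "dr_mean")
  if (!all(need %in% names(out))) {
    stop("tip-rate CSV must have columns: ", paste(need, collapse = ", "))
  }
  class(out) <- c("tip_rate_table", "data.frame")
  out
}

#' Correlation between tip rate and species age
#'
#' Tests the association between aggregated tip rates (`dr_mean`) and species
#' ages (terminal branch lengths). Rates are heavy-tailed, so the default is
#' a Spearman rank correlation; Pearson is available by flag. A strong
#' negative association is expected by construction (short terminal branches
#' inflate DR) and is the standard caveat when interpreting rate maps.
#'
#' @param table A `tip_rate_table`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A list with `estimate`, `p_value`, `method`, `n`.
#' @export
rate_age_correlation <- function(table, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (nrow(table) < 3) stop("need at least 3 species")
  x <- table$dr_mean; y <- table$age
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in rates or ages")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       method = method, n = nrow(table))
}
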