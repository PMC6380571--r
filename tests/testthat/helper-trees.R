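# Trees built in code for the tests.

# The small worked tree used throughout: four leaves, one internal clade,
# mutations on the clade stem and on one pendant edge.
tree_w <- function() {
  read_genealogy("((L1:0,L2:0,L3:1)A:1,L4:0)root;", dialect = "mutations")
}

# An ultrametric companion of the same shape (TMRCA 2 generations).
tree_w_times <- function() {
  read_genealogy("((L1:1,L2:1,L3:1)A:1,L4:2)root;", dialect = "times")
}

star_genealogy <- function(n, mutations) {
  new_genealogy(rep(n + 1L, n), seq_len(n), paste0("S", seq_len(n)),
                mutations = mutations)
}

# Random rooted genealogy with polytomies and unary nodes allowed, with
# Poisson(1) mutation counts; used for fuzz/property tests.
random_genealogy <- function(n, p_new = 0.3, mut_mean = 1) {
  parent <- integer(0)
  child <- integer(0)
  root <- n + 1L
  internals <- root
  nxt <- n + 2L
  for (i in seq_len(n)) {
    p <- internals[sample.int(length(internals), 1L)]
    if (stats::runif(1) < p_new) {
      parent <- c(parent, p)
      child <- c(child, nxt)
      p <- nxt
      internals <- c(internals, nxt)
      nxt <- nxt + 1L
    }
    parent <- c(parent, p)
    child <- c(child, i)
  }
  new_genealogy(parent, child, paste0("L", seq_len(n)),
                mutations = stats::rpois(length(parent), mut_mean))
}

# Matrix of Poisson mutation redraws on a fixed timed tree: one row per
# redraw, one column per edge.  Used as the vectorised Monte-Carlo oracle.
redraw_mutations <- function(g, mu, reps) {
  m <- length(g$time)
  matrix(stats::rpois(reps * m, rep(mu * g$time, each = reps)),
         nrow = reps, ncol = m)
}

# rho for every row of a redraw matrix, via the edge form.
rho_of_redraws <- function(g, draws) {
  as.numeric(draws %*% edge_leaf_counts(g)$leaves) / n_leaves(g)
}
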