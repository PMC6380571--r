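# Structural queries every estimator needs: root-to-leaf mutation sums L_i,
# per-edge descendant-leaf counts n_j, the TMRCA of a timed tree, and the
# infinite-sites haplotype partition.

# Per-edge descendant leaf counts n_j, as a plain integer vector.
.edge_ndesc <- function(g) {
  n <- n_leaves(g)
  ord <- .edge_preorder(g)
  cnt <- integer(max(c(g$parent, g$child)))
  cnt[seq_len(n)] <- 1L
  for (e in rev(ord)) cnt[g$parent[e]] <- cnt[g$parent[e]] + cnt[g$child[e]]
  cnt[g$child]
}

#' Mutations along each root-to-leaf path
#'
#' For leaf i, `L_i` is the sum of the mutation counts `R_j` over the edges
#' on the path from the MRCA down to leaf i.  The mean of these values over
#' all leaves is the rho statistic.
#'
#' @param g A `genealogy` with mutation counts.
#' @return A tibble with columns `leaf` (label) and `mutations` (`L_i`),
#'   one row per leaf in leaf-id order.
#' @examples
#' w <- read_genealogy("((L1:0,L2:0,L3:1)A:1,L4:0)root;", "mutations")
#' leaf_path_counts(w)
#' @export
leaf_path_counts <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  if (!has_mutations(g)) abort("genealogy carries no mutation counts")
  depth <- .node_depths(g, as.numeric(g$mutations))
  tibble::tibble(
    leaf = g$labels,
    mutations = as.integer(depth[seq_len(n_leaves(g))])
  )
}

#' Leaves descended from each edge
#'
#' `n_j` is the number of leaves whose root-to-leaf path contains edge j;
#' it is the weight edge j receives in the edge form of rho and in the
#' Saillard standard-error estimator.
#'
#' @param g A `genealogy`.
#' @return A tibble with columns `edge`, `parent`, `child`, `leaves` (`n_j`).
#' @export
edge_leaf_counts <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  tibble::tibble(
    edge = seq_along(g$parent),
    parent = g$parent,
    child = g$child,
    leaves = .edge_ndesc(g)
  )
}

#' TMRCA of a time-annotated genealogy
#'
#' Returns the common root-to-leaf time sum of an ultrametric genealogy, in
#' generations.
#'
#' @param g A `genealogy` with time lengths.
#' @param tol Relative ultrametricity tolerance (default 1e-9).
#' @return The TMRCA in generations.
#' @export
tmrca_from_times <- function(g, tol = 1e-9) {
  stopifnot(inherits(g, "genealogy"))
  if (!has_times(g)) abort("genealogy carries no time lengths")
  .check_ultrametric(g, tol)
}

#' Partition of the leaves into identical haplotypes
#'
#' Under the infinite-sites model every mutation is a unique, identifiable
#' event, so a leaf's haplotype is determined by the set of mutated edges on
#' its root path.  Two leaves carry the same haplotype exactly when every
#' edge in the symmetric difference of their root paths bears zero
#' mutations.  Each block reports its multiplicity `f` and its mutational
#' distance from the root `root_mutations` (shared by all members).
#'
#' @param g A `genealogy` with mutation counts.
#' @return A tibble with one row per haplotype block: `block` (id),
#'   `leaves` (list-column of leaf labels), `f` (block size) and
#'   `root_mutations`.
#' @examples
#' w <- read_genealogy("((L1:0,L2:0,L3:1)A:1,L4:0)root;", "mutations")
#' haplotype_partition(w)
#' @export
haplotype_partition <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  if (!has_mutations(g)) abort("genealogy carries no mutation counts")
  hp <- .hap_blocks(g)
  tibble::tibble(
    block = seq_along(hp$f),
    leaves = lapply(hp$members, function(i) g$labels[i]),
    f = hp$f,
    root_mutations = hp$ell
  )
}

# Shared core: blocks of leaf ids keyed by the set of mutated root-path
# edges, with multiplicities f_h and root distances ell_h.
.hap_blocks <- function(g) {
  n <- n_leaves(g)
  ord <- .edge_preorder(g)
  top <- max(c(g$parent, g$child))
  key <- character(top)
  ell <- integer(top)
  for (e in ord) {
    p <- g$parent[e]
    ch <- g$child[e]
    r <- g$mutations[e]
    key[ch] <- if (r > 0L) paste0(key[p], ",", e) else key[p]
    ell[ch] <- ell[p] + r
  }
  members <- split(seq_len(n), key[seq_len(n)])
  names(members) <- NULL
  list(
    members = members,
    f = lengths(members),
    ell = vapply(members, function(i) ell[i[1L]], integer(1))
  )
}
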