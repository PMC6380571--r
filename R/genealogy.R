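#' @importFrom rlang abort .data
#' @importFrom stats rexp rpois qnorm setNames
#' @importFrom utils write.table
NULL

#' Construct a mutation-annotated genealogy
#'
#' A `genealogy` is a rooted (possibly multifurcating) tree whose edges carry
#' an integer mutation count and, optionally, a time length in generations.
#' Leaves are numbered `1..n` and carry labels; internal node ids are larger
#' than `n`; the root is the most recent common ancestor (MRCA) of the
#' leaves.  Most users will build genealogies with [read_genealogy()] or
#' [simulate_genealogy()] rather than calling this constructor directly.
#'
#' @param parent,child Integer vectors, one entry per edge, giving the parent
#'   and child node id of each edge.
#' @param labels Character vector of leaf labels; leaf `i` has label
#'   `labels[i]`.
#' @param mutations Integer vector of per-edge mutation counts, or `NULL`
#'   when the genealogy carries no mutation annotation yet.
#' @param time Numeric vector of per-edge time lengths in generations, or
#'   `NULL`.  When present the genealogy must be ultrametric: every
#'   root-to-leaf time sum must equal a common value within a relative
#'   tolerance of 1e-9.
#' @param validate Check the structural invariants (default `TRUE`).
#'
#' @return An object of class `genealogy`.
#' @seealso [read_genealogy()], [edge_table()], [simulate_genealogy()]
#' @export
new_genealogy <- function(parent, child, labels, mutations = NULL,
                          time = NULL, validate = TRUE) {
  g <- structure(
    list(
      parent = as.integer(parent),
      child = as.integer(child),
      labels = as.character(labels),
      mutations = if (!is.null(mutations)) as.integer(mutations),
      time = if (!is.null(time)) as.numeric(time)
    ),
    class = "genealogy"
  )
  if (validate) validate_genealogy(g)
  g
}

#' Number of leaves of a genealogy
#' @param g A `genealogy`.
#' @return Integer leaf count `n`.
#' @export
n_leaves <- function(g) length(g$labels)

#' Root node id of a genealogy
#' @param g A `genealogy`.
#' @return Integer node id of the MRCA.
#' @export
root_node <- function(g) {
  r <- setdiff(unique(g$parent), g$child)
  if (length(r) != 1L) abort("genealogy must have exactly one root")
  r
}

has_times <- function(g) !is.null(g$time)
has_mutations <- function(g) !is.null(g$mutations)

validate_genealogy <- function(g) {
  n <- n_leaves(g)
  m <- length(g$parent)
  if (n < 1L) abort("a genealogy needs at least one leaf")
  if (length(g$child) != m) abort("parent and child must have equal length")
  if (anyDuplicated(g$child)) {
    abort("each node may have at most one parent (tree is not acyclic)")
  }
  nodes <- unique(c(g$parent, g$child))
  if (length(nodes) != m + 1L) abort("genealogy must be connected")
  r <- root_node(g)
  if (r <= n) abort("the root may not be a leaf with other leaves present")
  if (!all(seq_len(n) %in% g$child)) {
    abort("every leaf must be reachable from the root")
  }
  if (has_mutations(g)) {
    if (length(g$mutations) != m) abort("one mutation count per edge required")
    if (anyNA(g$mutations) || any(g$mutations < 0L)) {
      abort("mutation counts must be non-negative integers")
    }
  }
  if (has_times(g)) {
    if (length(g$time) != m) abort("one time length per edge required")
    if (anyNA(g$time) || any(g$time < 0)) {
      abort("time lengths must be non-negative")
    }
    .check_ultrametric(g)
  }
  invisible(g)
}

# Root-to-leaf sums of an arbitrary per-edge quantity `w`; returns a vector
# indexed by node id (only leaf entries are meaningful to callers).
.node_depths <- function(g, w) {
  ord <- .edge_preorder(g)
  depth <- numeric(max(c(g$parent, g$child)))
  for (e in ord) depth[g$child[e]] <- depth[g$parent[e]] + w[e]
  depth
}

# Edge indices ordered so every edge's parent node is visited first.
.edge_preorder <- function(g) {
  m <- length(g$parent)
  kids <- split(seq_len(m), g$parent)
  ord <- integer(m)
  stack <- root_node(g)
  k <- 0L
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    es <- kids[[as.character(nd)]]
    for (e in es) {
      k <- k + 1L
      ord[k] <- e
      ch <- g$child[e]
      if (ch > n_leaves(g)) stack <- c(stack, ch)
    }
  }
  ord
}

.check_ultrametric <- function(g, tol = 1e-9) {
  depth <- .node_depths(g, g$time)
  d <- depth[seq_len(n_leaves(g))]
  tmrca <- max(d)
  spread <- tmrca - min(d)
  if (spread > tol * max(tmrca, 1e-300) && !(tmrca == 0)) {
    abort(sprintf(
      "genealogy is not ultrametric: root-to-leaf times range over [%g, %g]",
      min(d), tmrca
    ))
  }
  tmrca
}

#' Per-edge table of a genealogy
#'
#' @param g A `genealogy`.
#' @return A tibble with one row per edge: `edge` (id, the storage order),
#'   `parent`, `child`, `mutations` (if annotated), `time` (if annotated)
#'   and `leaves`, the number of leaves descended from the edge.
#' @export
edge_table <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  out <- tibble::tibble(
    edge = seq_along(g$parent),
    parent = g$parent,
    child = g$child,
    leaves = .edge_ndesc(g)
  )
  if (has_mutations(g)) out$mutations <- g$mutations
  if (has_times(g)) out$time <- g$time
  out
}

#' @export
print.genealogy <- function(x, ...) {
  n <- n_leaves(x)
  ann <- c(
    if (has_mutations(x)) sprintf("%d mutations", sum(x$mutations)),
    if (has_times(x)) sprintf("TMRCA %.4g generations", tmrca_from_times(x))
  )
  cat(sprintf(
    "<genealogy> %d leaves, %d edges%s\n", n, length(x$parent),
    if (length(ann)) paste0(" (", paste(ann, collapse = ", "), ")") else ""
  ))
  invisible(x)
}

#' Read a mutation- or time-annotated genealogy from newick
#'
#' The newick branch-length field is interpreted according to `dialect`:
#' `"mutations"` reads integer mutation counts per edge, `"times"` reads
#' edge durations in generations (and requires the tree to be ultrametric).
#' The outermost newick node is taken to be the MRCA; a nonzero root edge is
#' an error because mutations above the MRCA play no role in rho dating.
#'
#' @param x A newick string, or the path of a file containing a single
#'   newick tree (trailing semicolon required).
#' @param dialect `"mutations"` or `"times"`; never guessed.
#' @param round In the mutations dialect, permit branch lengths that are
#'   within 1e-6 of an integer to be rounded; anything farther is always an
#'   error, and without `round = TRUE` any non-integer length is an error.
#' @return A [new_genealogy()] object.
#' @examples
#' g <- read_genealogy("(A:1,B:1):0;", dialect = "mutations")
#' edge_table(g)
#' @export
read_genealogy <- function(x, dialect = c("mutations", "times"),
                           round = FALSE) {
  dialect <- match.arg(dialect)
  stopifnot(is.character(x), length(x) == 1L)
  txt <- if (grepl("\\(", x) || grepl(";", x)) x else {
    if (!file.exists(x)) abort(sprintf("file not found: %s", x))
    paste(readLines(x, warn = FALSE), collapse = "")
  }
  if (!grepl(";\\s*$", txt)) abort("newick input must end with a semicolon")
  phy <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(phy)) abort("could not parse newick input")
  if (is.null(phy$edge.length) || anyNA(phy$edge.length) ||
      any(!is.finite(phy$edge.length))) {
    abort("every edge must carry a branch length")
  }
  if (!is.null(phy$root.edge) && phy$root.edge != 0) {
    abort("nonzero root edge: mutations/time above the MRCA are not supported")
  }
  if (any(phy$edge.length < 0)) abort("negative branch length")
  el <- phy$edge.length
  if (dialect == "mutations") {
    dev <- abs(el - round(el))
    if (any(dev > 0) && !round) {
      abort("non-integer mutation count in mutations dialect (see `round`)")
    }
    if (any(dev > 1e-6)) {
      abort("branch length differs from an integer by more than 1e-6")
    }
    new_genealogy(phy$edge[, 1L], phy$edge[, 2L], phy$tip.label,
                  mutations = as.integer(round(el)))
  } else {
    new_genealogy(phy$edge[, 1L], phy$edge[, 2L], phy$tip.label, time = el)
  }
}

# genealogy -> ape "phylo", with edge lengths taken from the chosen dialect.
as_phylo <- function(g, dialect = c("mutations", "times")) {
  dialect <- match.arg(dialect)
  el <- if (dialect == "mutations") {
    if (!has_mutations(g)) abort("genealogy carries no mutation counts")
    as.numeric(g$mutations)
  } else {
    if (!has_times(g)) abort("genealogy carries no time lengths")
    g$time
  }
  n <- n_leaves(g)
  internal <- sort(unique(g$parent))
  r <- root_node(g)
  # ape convention: tips 1..n, root n+1, remaining internal nodes follow
  map <- integer(max(internal))
  map[r] <- n + 1L
  map[setdiff(internal, r)] <- n + 1L + seq_along(setdiff(internal, r))
  to_ape <- function(v) ifelse(v <= n, v, map[v])
  phy <- list(
    edge = cbind(to_ape(g$parent), to_ape(g$child)),
    tip.label = g$labels,
    Nnode = length(internal),
    edge.length = el
  )
  class(phy) <- "phylo"
  phy
}

#' Write a genealogy as a newick string
#'
#' @inheritParams read_genealogy
#' @param g A `genealogy` carrying the annotation the dialect asks for.
#' @param file Optional path; when given the newick string is also written
#'   to the file.
#' @return The newick string, invisibly when `file` is given.
#' @export
write_genealogy <- function(g, dialect = c("mutations", "times"),
                            file = NULL) {
  dialect <- match.arg(dialect)
  txt <- ape::write.tree(as_phylo(g, dialect))
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
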