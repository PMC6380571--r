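# Constant-size Kingman coalescent simulation with infinite-sites Poisson
# mutation dropping.  Haploid convention throughout: while k lineages
# remain, the waiting time to the next merger is Exponential with rate
# k(k-1)/(2N) generations, and theta = 2 N mu.

#' Whole-sequence per-generation mutation rate from a per-site yearly rate
#'
#' Converts a per-base-pair per-year substitution rate into the total
#' per-lineage per-generation rate of the whole sequence:
#' `rate * generation_time * seq_len`.  With the defaults (1.8e-7 per bp
#' per year, 26-year generations, 500 bp) this gives 0.00234 per
#' generation.
#'
#' @param rate_per_bp_per_year Substitution rate per base pair per year.
#' @param generation_time Generation time in years.
#' @param seq_len Sequence length in base pairs.
#' @return Mutation rate per lineage per generation (whole sequence).
#' @export
per_generation_rate <- function(rate_per_bp_per_year = 1.8e-7,
                                generation_time = 26, seq_len = 500) {
  rate_per_bp_per_year * generation_time * seq_len
}

#' Scaled mutation parameter theta for haploids
#'
#' `theta = 2 N mu` for a haploid population of size `N` and whole-sequence
#' rate `mu`; the default study conditions (N = 1000, mu = 0.00234) give 4.68.
#'
#' @param N Haploid population size.
#' @param mu Mutation rate per lineage per generation.
#' @return theta.
#' @export
theta_haploid <- function(N = 1000, mu = per_generation_rate()) 2 * N * mu

#' Configuration of a coalescent simulation experiment
#'
#' Bundles the study conditions: haploid sample size `n`, haploid
#' population size `N`, the whole-sequence mutation rate `mu` (or,
#' exclusively, `theta`, from which `mu = theta/(2N)` is derived), the
#' replicate count and the master seed.
#'
#' @param n Haploid sample size (>= 2).
#' @param N Haploid population size (> 0).
#' @param mu Mutation rate per lineage per generation (>= 0); give either
#'   `mu` or `theta`, not both.
#' @param theta Scaled mutation parameter `2 N mu`.
#' @param reps Number of replicates (>= 1).
#' @param seed Master seed (integer).
#' @return A list of class `coalescent_config` with fields `n`, `N`, `mu`,
#'   `theta`, `reps`, `seed`.
#' @export
coalescent_config <- function(n = 100, N = 1000, mu = NULL, theta = NULL,
                              reps = 10000, seed = 1) {
  if (is.null(mu) == is.null(theta)) {
    abort("give exactly one of mu and theta")
  }
  if (is.null(mu)) mu <- theta / (2 * N)
  if (n < 2) abort("n must be at least 2")
  if (N <= 0) abort("N must be positive")
  if (mu < 0) abort("mu must be non-negative")
  if (reps < 1) abort("reps must be at least 1")
  structure(
    list(n = as.integer(n), N = N, mu = mu, theta = 2 * N * mu,
         reps = as.integer(reps), seed = as.integer(seed)),
    class = "coalescent_config"
  )
}

# Order-independent per-replicate seeds: one draw from the master seed.
# Every derived seed stays below 2^31.
.replicate_seeds <- function(seed, reps) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max, reps)
}

#' Simulate a constant-size Kingman coalescent genealogy
#'
#' While `k > 1` lineages remain, a waiting time is drawn from an
#' Exponential distribution with rate `k(k-1)/(2N)` generations and a
#' uniformly random pair of lineages is merged.  The result is an
#' ultrametric, binary, time-annotated genealogy whose TMRCA has
#' expectation `2N(1 - 1/n)` generations.  Randomness comes from R's
#' global RNG; seed with [set.seed()] (the experiment drivers manage
#' per-replicate seeds themselves).
#'
#' @param n Haploid sample size (>= 2).
#' @param N Haploid population size (> 0).
#' @return A time-annotated `genealogy` with leaves `t1..tn`.
#' @examples
#' set.seed(1)
#' g <- simulate_genealogy(5, N = 1000)
#' tmrca_from_times(g)
#' @export
simulate_genealogy <- function(n, N) {
  if (n < 2) abort("n must be at least 2 to coalesce")
  if (N <= 0) abort("N must be positive")
  n <- as.integer(n)
  active <- seq_len(n)
  node_age <- numeric(2L * n - 1L)
  parent <- integer(2L * n - 2L)
  child <- integer(2L * n - 2L)
  nxt <- n + 1L
  e <- 0L
  t <- 0
  k <- n
  while (k > 1L) {
    t <- t + rexp(1L, k * (k - 1) / (2 * N))
    pick <- sample.int(k, 2L)
    node_age[nxt] <- t
    child[e + 1L] <- active[pick[1L]]
    child[e + 2L] <- active[pick[2L]]
    parent[e + 1L] <- nxt
    parent[e + 2L] <- nxt
    e <- e + 2L
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
    k <- k - 1L
  }
  new_genealogy(parent, child, labels = paste0("t", seq_len(n)),
                time = node_age[parent] - node_age[child],
                validate = FALSE)
}

#' Drop infinite-sites mutations onto a timed genealogy
#'
#' Each edge receives `R_j ~ Poisson(mu * T_j)` mutations independently.
#' Under the infinite-sites model every mutation is a unique event, so the
#' counts fully determine the leaf haplotypes.
#'
#' @param g A time-annotated `genealogy`.
#' @param mu Mutation rate per lineage per generation (>= 0).
#' @return The genealogy with mutation counts added (times retained).
#' @export
drop_mutations <- function(g, mu) {
  stopifnot(inherits(g, "genealogy"))
  if (!has_times(g)) abort("genealogy carries no time lengths")
  if (mu < 0) abort("mu must be non-negative")
  g$mutations <- rpois(length(g$time), mu * g$time)
  g
}

#' Export a simulated genealogy as sequence and tree fixtures
#'
#' Assigns each mutation a distinct site drawn without replacement from
#' `1..seq_len` (infinite sites at finite length) and a derived allele
#' differing from the ancestral one, then writes a FASTA alignment of the
#' leaf haplotypes (the root sequence is included as `MRCA`) and newick
#' files in both dialects.
#'
#' @param g A `genealogy` with mutation counts; when times are also present
#'   the times-dialect newick is written too.
#' @param seq_len Sequence length in base pairs (default 500); the total
#'   mutation count must not exceed it.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"fixture"`).
#' @return Invisibly, a named character vector of the files written.
#' @export
export_fixture <- function(g, seq_len = 500, dir = ".", prefix = "fixture") {
  stopifnot(inherits(g, "genealogy"))
  if (!has_mutations(g)) abort("genealogy carries no mutation counts")
  total <- sum(g$mutations)
  if (total > seq_len) {
    abort(sprintf(
      "infinite-sites violation: %d mutations cannot occupy %d sites",
      total, seq_len
    ))
  }
  bases <- c("a", "c", "g", "t")
  root_seq <- sample(bases, seq_len, replace = TRUE)
  sites <- sample.int(seq_len, total)
  alleles <- vapply(sites, function(s) {
    sample(setdiff(bases, root_seq[s]), 1L)
  }, character(1))
  # walk the tree applying each edge's mutations cumulatively
  ord <- .edge_preorder(g)
  n <- n_leaves(g)
  seqs <- vector("list", max(c(g$parent, g$child)))
  seqs[[root_node(g)]] <- root_seq
  offs <- c(0L, cumsum(g$mutations))
  for (e in ord) {
    s <- seqs[[g$parent[e]]]
    if (g$mutations[e] > 0L) {
      idx <- (offs[e] + 1L):offs[e + 1L]
      s[sites[idx]] <- alleles[idx]
    }
    seqs[[g$child[e]]] <- s
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat <- do.call(rbind, c(list(MRCA = root_seq), seqs[seq_len(n)]))
  rownames(mat) <- c("MRCA", g$labels)
  fasta <- file.path(dir, paste0(prefix, ".fasta"))
  ape::write.FASTA(ape::as.DNAbin(mat), fasta)
  files <- c(fasta = fasta)
  nwk_m <- file.path(dir, paste0(prefix, "_mutations.nwk"))
  write_genealogy(g, "mutations", file = nwk_m)
  files["newick_mutations"] <- nwk_m
  if (has_times(g)) {
    nwk_t <- file.path(dir, paste0(prefix, "_times.nwk"))
    write_genealogy(g, "times", file = nwk_t)
    files["newick_times"] <- nwk_t
  }
  invisible(files)
}
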