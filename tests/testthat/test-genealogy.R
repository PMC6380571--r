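test_that("newick parsing honours the dialect and validates input", {
  g <- read_genealogy("(A:1,B:1):0;", dialect = "mutations")
  expect_equal(n_leaves(g), 2L)
  expect_equal(sort(g$mutations), c(1L, 1L))
  expect_null(g$time)

  gt <- read_genealogy("(A:100,B:100):0;", dialect = "times")
  expect_equal(tmrca_from_times(gt), 100)
  expect_null(gt$mutations)

  expect_error(read_genealogy("(A:1.5,B:1):0;", "mutations"), "non-integer")
  # the round flag rescues near-integers but nothing farther than 1e-6
  g3 <- read_genealogy("(A:1.0000001,B:1):0;", "mutations", round = TRUE)
  expect_equal(sort(g3$mutations), c(1L, 1L))
  expect_error(read_genealogy("(A:1.5,B:1):0;", "mutations", round = TRUE),
               "1e-6")
  expect_error(read_genealogy("(A:-1,B:1):0;", "mutations"), "negative")
  expect_error(read_genealogy("(A:1,B);", "mutations"), "branch length")
  expect_error(read_genealogy("(A:1,B:1):2;", "mutations"), "root edge")
  expect_error(read_genealogy("(A:1,B:1)", "mutations"), "semicolon")
})

test_that("write/read round-trips preserve the edge annotation multiset", {
  w <- tree_w()
  back <- read_genealogy(write_genealogy(w, "mutations"), "mutations")
  expect_equal(sort(back$mutations), sort(w$mutations))
  expect_equal(
    dplyr::arrange(leaf_path_counts(back), leaf),
    dplyr::arrange(leaf_path_counts(w), leaf)
  )

  gt <- read_genealogy("((A:50,B:50):50,C:100):0;", "times")
  back_t <- read_genealogy(write_genealogy(gt, "times"), "times")
  expect_equal(tmrca_from_times(back_t), tmrca_from_times(gt),
               tolerance = 1e-9)
  expect_equal(sort(back_t$time), sort(gt$time), tolerance = 1e-9)

  # dialect annotation must be present to write it
  expect_error(write_genealogy(w, "times"), "no time lengths")
  expect_error(write_genealogy(gt, "mutations"), "no mutation counts")
})

test_that("leaf path counts sum mutations along each root-to-leaf path", {
  counts <- leaf_path_counts(tree_w())
  expect_equal(
    setNames(counts$mutations, counts$leaf),
    c(L1 = 1L, L2 = 1L, L3 = 2L, L4 = 0L)
  )

  zero <- read_genealogy("((A:0,B:0):0,C:0):0;", "mutations")
  expect_true(all(leaf_path_counts(zero)$mutations == 0L))

  single <- read_genealogy("(A:3);", "mutations")
  expect_equal(leaf_path_counts(single)$mutations, 3L)
  expect_equal(rho_result(single)$rho, 3)
})

test_that("edge leaf counts give the Saillard weights n_j", {
  w <- tree_w()
  tab <- edge_leaf_counts(w)
  # the clade stem subtends 3 leaves, every other edge exactly 1
  expect_equal(sort(tab$leaves), c(1L, 1L, 1L, 1L, 3L))
  expect_equal(sum(tab$leaves[tab$parent == root_node(w)]), n_leaves(w))

  star <- star_genealogy(7, rep(1L, 7))
  expect_true(all(edge_leaf_counts(star)$leaves == 1L))
  two <- read_genealogy("(A:1,B:1):0;", "mutations")
  expect_true(all(edge_leaf_counts(two)$leaves == 1L))
})

test_that("tmrca_from_times requires ultrametric trees", {
  g <- read_genealogy("((A:50,B:50):50,C:100):0;", "times")
  expect_equal(tmrca_from_times(g), 100)
  expect_error(read_genealogy("(A:100,B:90):0;", "times"), "ultrametric")
  expect_error(tmrca_from_times(tree_w()), "no time lengths")
})

test_that("haplotype partition groups leaves by their mutated root paths", {
  hp <- haplotype_partition(tree_w())
  key <- lapply(seq_len(nrow(hp)), function(i) {
    list(sort(hp$leaves[[i]]), hp$f[i], hp$root_mutations[i])
  })
  expect_setequal(key, list(
    list(c("L1", "L2"), 2L, 1L),
    list("L3", 1L, 2L),
    list("L4", 1L, 0L)
  ))

  zero <- read_genealogy("((A:0,B:0):0,C:0):0;", "mutations")
  hp0 <- haplotype_partition(zero)
  expect_equal(nrow(hp0), 1L)
  expect_equal(hp0$f, 3L)
  expect_equal(hp0$root_mutations, 0L)

  star <- star_genealogy(6, rep(1L, 6))
  hps <- haplotype_partition(star)
  expect_equal(nrow(hps), 6L)
  expect_true(all(hps$f == 1L) && all(hps$root_mutations == 1L))
})

test_that("sum of leaf path counts equals the n_j-weighted mutation total", {
  set.seed(101)
  for (i in 1:50) {
    g <- random_genealogy(sample(2:25, 1))
    expect_identical(
      sum(leaf_path_counts(g)$mutations),
      sum(edge_leaf_counts(g)$leaves * g$mutations)
    )
  }
})

test_that("adding a mutation to an edge never merges haplotype blocks", {
  set.seed(202)
  for (i in 1:25) {
    g <- random_genealogy(sample(3:15, 1))
    before <- nrow(haplotype_partition(g))
    e <- sample.int(length(g$parent), 1)
    g$mutations[e] <- g$mutations[e] + 1L
    expect_gte(nrow(haplotype_partition(g)), before)
  }
})

test_that("structural invariants are enforced by the constructor", {
  # two parents for one node
  expect_error(
    new_genealogy(c(3L, 3L, 4L), c(1L, 2L, 1L), c("A", "B")),
    "at most one parent"
  )
  # disconnected extra component
  expect_error(
    new_genealogy(c(3L, 3L, 5L), c(1L, 2L, 6L), c("A", "B")),
    "connected"
  )
  expect_error(
    new_genealogy(c(3L, 3L), c(1L, 2L), c("A", "B"), mutations = c(-1L, 0L)),
    "non-negative"
  )
})
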