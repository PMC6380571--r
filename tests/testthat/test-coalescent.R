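test_that("the reference mutation parameters derive exactly", {
  expect_equal(per_generation_rate(1.8e-7, 26, 500), 0.00234)
  expect_equal(theta_haploid(1000, 0.00234), 4.68)
  expect_equal(per_generation_rate(), 0.00234)
})

test_that("coalescent_config derives theta from mu and vice versa", {
  cfg <- coalescent_config(n = 100, N = 1000, mu = 0.00234, reps = 10)
  expect_equal(cfg$theta, 4.68)
  cfg2 <- coalescent_config(n = 100, N = 1000, theta = 4.68, reps = 10)
  expect_equal(cfg2$mu, 0.00234)
  expect_error(coalescent_config(mu = 0.1, theta = 1), "exactly one")
  expect_error(coalescent_config(n = 1, mu = 0.1), "n")
  expect_error(coalescent_config(N = 0, mu = 0.1), "N")
  expect_error(coalescent_config(mu = -0.1), "mu")
  expect_error(coalescent_config(mu = 0.1, reps = 0), "reps")
})

test_that("simulated genealogies are ultrametric with the Kingman TMRCA", {
  # E[TMRCA] = 2N(1 - 1/n); checked within 4 Monte-Carlo standard errors
  for (case in list(list(n = 2, reps = 8000), list(n = 5, reps = 3000))) {
    set.seed(123)
    tm <- replicate(case$reps,
                    tmrca_from_times(simulate_genealogy(case$n, 1000)))
    expected <- 2 * 1000 * (1 - 1 / case$n)
    expect_lt(abs(mean(tm) - expected), 4 * sd(tm) / sqrt(case$reps))
  }
  set.seed(9)
  g <- simulate_genealogy(50, 1000)
  expect_silent(tmrca_from_times(g)) # ultrametric by construction
  expect_equal(n_leaves(g), 50L)
  expect_equal(length(g$parent), 98L) # binary: 2n - 2 edges
  expect_error(simulate_genealogy(1, 1000), "at least 2")
})

test_that("mutation dropping is conditionally Poisson on the edges", {
  set.seed(77)
  g <- simulate_genealogy(8, 800)
  expect_true(all(drop_mutations(g, 0)$mutations == 0L))
  expect_error(drop_mutations(tree_w(), 0.1), "time")

  mu <- 0.005
  reps <- 10000
  set.seed(78)
  draws <- redraw_mutations(g, mu, reps)
  total <- rowSums(draws)
  expect_lt(abs(mean(total) - mu * sum(g$time)),
            4 * sd(total) / sqrt(reps))
  # per-edge mean and variance agree (Poisson), on the longest edge
  e <- which.max(g$time)
  expect_lt(abs(mean(draws[, e]) - var(draws[, e])),
            4 * sd((draws[, e] - mean(draws[, e]))^2) / sqrt(reps))
  # same distribution as drop_mutations itself at one redraw
  set.seed(79)
  gm <- drop_mutations(g, mu)
  expect_true(all(gm$mutations >= 0L))
  expect_equal(gm$time, g$time)
})

test_that("identical config and seed give bit-identical records", {
  cfg <- coalescent_config(n = 10, N = 500, mu = 0.01, reps = 25, seed = 31)
  a <- run_bias_experiment(cfg)
  b <- run_bias_experiment(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$bias, b$bias)
})

test_that("fixture export writes infinite-sites consistent alignments", {
  withr::local_seed(11)
  dir <- withr::local_tempdir()

  # no mutations: every sequence equals the root
  zero <- read_genealogy("((A:0,B:0):0,C:0):0;", "mutations")
  f0 <- export_fixture(zero, seq_len = 100, dir = dir, prefix = "zero")
  aln <- as.character(ape::read.FASTA(f0[["fasta"]]))
  expect_true(all(vapply(aln, identical, TRUE, aln[["MRCA"]])))

  # tree W: L3 differs from the root at exactly its 2 path mutations
  fw <- export_fixture(tree_w(), seq_len = 500, dir = dir, prefix = "w")
  aln <- as.character(ape::read.FASTA(fw[["fasta"]]))
  diffs <- vapply(c("L1", "L2", "L3", "L4"), function(l) {
    sum(aln[[l]] != aln[["MRCA"]])
  }, numeric(1))
  expect_equal(unname(diffs), c(1, 1, 2, 0))
  # L1 and L2 share the same haplotype
  expect_identical(aln[["L1"]], aln[["L2"]])
  # the mutations-dialect newick round-trips
  back <- read_genealogy(fw[["newick_mutations"]], "mutations")
  expect_equal(sort(back$mutations), sort(tree_w()$mutations))

  # more mutations than sites is an infinite-sites violation
  big <- star_genealogy(3, c(200L, 200L, 200L))
  expect_error(export_fixture(big, seq_len = 500, dir = dir), "infinite-sites")
})
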