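# rhodate

Molecular dating of clades with the **rho statistic**, for
phylogeographers and population geneticists who date mtDNA or
Y-chromosome haplogroups from mutation-annotated trees.

Given the rooted genealogy of a clade whose edge *j* carries *R_j*
mutations, rho is the mean mutational distance from the root (the
ancestral haplotype) to the *n* sampled sequences,

    rho = (1/n) Σ_i L_i = (1/n) Σ_j n_j R_j,

where *L_i* sums the mutations on the root-to-leaf-*i* path and *n_j*
counts the leaves below edge *j*.  Under a Poisson molecular clock with
whole-sequence rate μ per generation, `rho/mu` is an **unbiased**
estimator of the clade's TMRCA.  The package provides:

* the rho statistic with three estimated standard errors — the Saillard
  edge-weighted plug-in `sqrt(Σ n_j² R_j)/n`, a reconstruction of Cox's
  star-of-distinct-haplotypes expression `sqrt(Σ f_h² ℓ_h)/n`, and the
  star-genealogy lower bound `sqrt(rho/n)` — which satisfy
  `lower ≤ cox ≤ saillard` on every tree;
* Wald confidence intervals `(rho ± z·e.s.e.)/mu` on the age scale and
  delta-method propagation of mutation-rate uncertainty;
* newick I/O in two dialects (branch lengths as integer mutation counts,
  or as time in generations) with haplotype-partition, path-count and
  edge-weight queries, all returning tibbles;
* a constant-size Kingman coalescent simulator (haploid convention,
  θ = 2Nμ) with infinite-sites Poisson mutation dropping and FASTA/newick
  fixture export;
* an experiment harness measuring the bias of `rho/mu` and the empirical
  coverage of the three Wald intervals as a function of θ, with
  `tidy()`/`glance()`/`autoplot()` methods throughout, plus an
  `exec/rhodate` command-line wrapper.

## Worked example

```r
library(rhodate)

w <- read_genealogy("((L1:0,L2:0,L3:1)A:1,L4:0)root;", dialect = "mutations")
rho_result(w)
#> <rho_result> n = 4 leaves
#>   rho           1
#>   e.s.e. saillard 0.790569 | cox 0.612372 | lower 0.5

glance(estimate_age(w, mu = 0.01, se_mu = 0.001))
#> # A tibble: 1 × 9
#>     rho     n    mu se_method level t_hat ci_low ci_high se_t_hat_delta
#>   <dbl> <int> <dbl> <chr>     <dbl> <dbl>  <dbl>   <dbl>          <dbl>
#> 1     1     4  0.01 saillard   0.95   100  -54.9    255.           79.7
```

Four sequences sit a mean of `rho = 1` mutation from the root.  The
Saillard standard error (0.79 mutations) exceeds the haplotype-level
reconstruction (0.61) and the star-tree floor (0.5) because the shared
internal edge correlates three of the four root paths.  At μ = 0.01 per
generation the clade age estimate is 100 generations; the 95% Wald
interval is wide and dips below zero — rho intervals are reported
untruncated — and folding in a rate uncertainty of se(μ) = 0.001 gives a
delta-method age SE of 79.7 generations.

The simulation study at its native scale:

```r
cfg <- coalescent_config(n = 100, N = 1000, mu = per_generation_rate(),
                         reps = 10000, seed = 1)   # theta = 4.68
run_bias_experiment(cfg)
#> <bias_result> 10000 replicates (n = 100, N = 1000, mu = 0.00234, theta = 4.68)
#>   mean(t_hat - t_true)  2.813 generations
#>   origin slope          1.00088 (95% CI 0.995326..1.00643)
```

A mean signed error of 2.8 generations against a true TMRCA averaging
~1980 generations, and an origin-regression slope indistinguishable from
1: `rho/mu` is unbiased, and the residual is Monte-Carlo noise.

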