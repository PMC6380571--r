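Package: rhodate
Title: Molecular Dating with the Rho Statistic
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the age (time to the most recent common ancestor) of a
    clade from a mutation-annotated genealogy using the rho statistic, the
    mean number of mutations from the root to each sampled sequence, divided
    by the mutation rate.  Provides three estimators of the standard error of
    rho (the Saillard edge-weighted estimator, a reconstruction of Cox's
    star-of-distinct-haplotypes expression, and the star-genealogy lower
    bound), Wald confidence intervals on the age scale, and delta-method
    propagation of mutation-rate uncertainty.  Includes a constant-size
    Kingman coalescent simulator with infinite-sites Poisson mutation
    dropping and an experiment harness that verifies the unbiasedness of
    rho-based ages and measures confidence-interval coverage as a function of
    the scaled mutation parameter theta.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    optparse,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
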