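# The rho statistic and its standard-error estimators.
#
# rho is the mean number of mutations over all root-to-leaf paths,
#   rho = (1/n) sum_i L_i = (1/n) sum_j n_j R_j,
# and rho/mu is an unbiased estimator of the TMRCA because
# L_i | {T_j} ~ Poisson(mu T) for every leaf i of an ultrametric tree.
# Three estimated standard errors (e.s.e.) of rho are provided:
#   * saillard: sqrt((1/n^2) sum_j n_j^2 R_j), the plug-in for
#     Var(rho | tree) = (1/n^2) sum_j n_j^2 mu T_j; accounts for the shared
#     ancestry (correlation of the L_i) through the edge weights n_j.
#   * cox: the Saillard formula applied to the fictitious star tree whose
#     "leaves" are the distinct haplotypes, sqrt((1/n^2) sum_h f_h^2 ell_h).
#     This is a reconstruction of Cox's expression from its verbal
#     characterisation; it ignores mutations shared through internal
#     structure above the haplotype level.
#   * lower: sqrt(rho/n), exact only for a perfectly star-like genealogy.
# On every tree, lower <= cox <= saillard.

# Fast numeric core used by the experiment loops: returns the statistics
# without building any tibble.  `ndesc` may be precomputed.
.rho_stats <- function(g, ndesc = .edge_ndesc(g)) {
  n <- n_leaves(g)
  r <- g$mutations
  rho <- sum(ndesc * r) / n
  hp <- .hap_blocks(g)
  c(
    rho = rho,
    ese_saillard = sqrt(sum(as.numeric(ndesc)^2 * r)) / n,
    ese_cox = sqrt(sum(as.numeric(hp$f)^2 * hp$ell)) / n,
    ese_lower = sqrt(rho / n)
  )
}

#' The rho statistic with its three standard-error estimators
#'
#' Computes rho both as the mean of the leaf path counts `L_i` and as the
#' edge-weighted sum `(1/n) sum_j n_j R_j`; the two forms must agree exactly
#' (they are the same integer total) and the agreement is asserted.
#'
#' @param g A `genealogy` with mutation counts.
#' @return An object of class `rho_result` with fields `rho`, `n`,
#'   `ese_saillard`, `ese_cox`, `ese_lower` and `per_edge` (a tibble of
#'   edge id, `leaves` = n_j, `mutations` = R_j).  [glance()] returns the
#'   one-row summary, [tidy()] the per-edge table.
#' @examples
#' w <- read_genealogy("((L1:0,L2:0,L3:1)A:1,L4:0)root;", "mutations")
#' rho_result(w)
#' @export
rho_result <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  if (!has_mutations(g)) abort("genealogy carries no mutation counts")
  n <- n_leaves(g)
  ndesc <- .edge_ndesc(g)
  leaf_total <- sum(leaf_path_counts(g)$mutations)
  edge_total <- sum(ndesc * g$mutations)
  stopifnot(leaf_total == edge_total) # leaf form == edge form, exactly
  s <- .rho_stats(g, ndesc)
  structure(
    list(
      rho = unname(s["rho"]),
      n = n,
      ese_saillard = unname(s["ese_saillard"]),
      ese_cox = unname(s["ese_cox"]),
      ese_lower = unname(s["ese_lower"]),
      per_edge = tibble::tibble(
        edge = seq_along(g$parent),
        leaves = ndesc,
        mutations = g$mutations
      )
    ),
    class = "rho_result"
  )
}

#' @export
print.rho_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<rho_result> n = %d leaves\n",
      "  rho           %.6g\n",
      "  e.s.e. saillard %.6g | cox %.6g | lower %.6g\n"
    ),
    x$n, x$rho, x$ese_saillard, x$ese_cox, x$ese_lower
  ))
  invisible(x)
}

#' @rdname rho_result
#' @param x A `rho_result`.
#' @param ... Unused.
#' @method glance rho_result
#' @export
glance.rho_result <- function(x, ...) {
  tibble::tibble(
    rho = x$rho, n = x$n,
    ese_saillard = x$ese_saillard,
    ese_cox = x$ese_cox,
    ese_lower = x$ese_lower
  )
}

#' @rdname rho_result
#' @method tidy rho_result
#' @export
tidy.rho_result <- function(x, ...) x$per_edge

#' Standard-error estimators of rho
#'
#' `ese_saillard()` is the edge-weighted plug-in estimator
#' `sqrt((1/n^2) sum_j n_j^2 R_j)`, which accounts for the dependence of the
#' leaf path counts through shared edges.  `ese_cox()` applies the same
#' formula to the star tree of distinct haplotypes (multiplicities `f_h` at
#' root distances `ell_h`); it is a reconstruction of the expression Cox
#' used and ignores correlation above the haplotype level.  `ese_lower()`
#' is `sqrt(rho/n)`, the value for a perfectly star-like genealogy and a
#' lower bound for the other two.
#'
#' @param g A `genealogy` with mutation counts.
#' @return The estimated standard error of rho, in mutations.
#' @examples
#' w <- read_genealogy("((L1:0,L2:0,L3:1)A:1,L4:0)root;", "mutations")
#' c(ese_lower(w), ese_cox(w), ese_saillard(w))
#' @export
ese_saillard <- function(g) rho_result(g)$ese_saillard

#' @rdname ese_saillard
#' @export
ese_cox <- function(g) rho_result(g)$ese_cox

#' @rdname ese_saillard
#' @export
ese_lower <- function(g) rho_result(g)$ese_lower

#' Estimate a clade age from rho with a Wald confidence interval
#'
#' The TMRCA point estimate is `rho/mu` and the interval is
#' `(rho +/- z * e.s.e.)/mu`, with `z` the exact standard-normal two-sided
#' quantile for `level` (1.959964 at 0.95, not the rounded 1.96).  The lower
#' end is not truncated at zero by default, because coverage experiments
#' must evaluate the Wald interval as defined; set `clamp_zero = TRUE` for
#' reporting.
#'
#' @param g A `genealogy` with mutation counts.
#' @param mu Total mutation rate of the sequence per lineage per generation;
#'   must be positive.
#' @param se_mu Optional standard error of `mu`; when given, the
#'   delta-method standard error of the age is attached (see
#'   [age_se_delta()]).
#' @param se_method Which e.s.e. of rho to use: `"saillard"` (default),
#'   `"cox"` or `"lower"`.
#' @param level Confidence level in (0, 1); default 0.95.
#' @param clamp_zero Truncate the lower interval end at zero.
#' @return An object of class `age_estimate`; [glance()] returns it as a
#'   one-row tibble with `t_hat`, `ci_low`, `ci_high` in generations.
#' @examples
#' w <- read_genealogy("((L1:0,L2:0,L3:1)A:1,L4:0)root;", "mutations")
#' glance(estimate_age(w, mu = 0.01))
#' @export
estimate_age <- function(g, mu, se_mu = NULL,
                         se_method = c("saillard", "cox", "lower"),
                         level = 0.95, clamp_zero = FALSE) {
  se_method <- match.arg(se_method)
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0) {
    abort("mu must be a single positive number")
  }
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    abort("level must lie in (0, 1)")
  }
  rr <- rho_result(g)
  ese <- switch(se_method,
    saillard = rr$ese_saillard,
    cox = rr$ese_cox,
    lower = rr$ese_lower
  )
  z <- qnorm(1 - (1 - level) / 2)
  t_hat <- rr$rho / mu
  ci_low <- (rr$rho - z * ese) / mu
  ci_high <- (rr$rho + z * ese) / mu
  if (clamp_zero) ci_low <- max(0, ci_low)
  structure(
    list(
      t_hat = t_hat, ci_low = ci_low, ci_high = ci_high,
      level = level, se_method = se_method, mu = mu, se_mu = se_mu,
      se_t_hat_delta = if (!is.null(se_mu)) {
        age_se_delta(rr$rho, ese, mu, se_mu)
      },
      rho = rr
    ),
    class = "age_estimate"
  )
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf(
    "<age_estimate> t_hat = %.6g generations, %g%% CI [%.6g, %.6g] (%s e.s.e.)\n",
    x$t_hat, 100 * x$level, x$ci_low, x$ci_high, x$se_method
  ))
  if (!is.null(x$se_t_hat_delta)) {
    cat(sprintf("  delta-method SE(t_hat) = %.6g generations\n",
                x$se_t_hat_delta))
  }
  invisible(x)
}

#' @rdname estimate_age
#' @param x An `age_estimate`.
#' @param ... Unused.
#' @method glance age_estimate
#' @export
glance.age_estimate <- function(x, ...) {
  tibble::tibble(
    rho = x$rho$rho, n = x$rho$n,
    mu = x$mu, se_method = x$se_method, level = x$level,
    t_hat = x$t_hat, ci_low = x$ci_low, ci_high = x$ci_high,
    se_t_hat_delta = x$se_t_hat_delta %||% NA_real_
  )
}

#' @rdname estimate_age
#' @method tidy age_estimate
#' @export
tidy.age_estimate <- function(x, ...) glance.age_estimate(x, ...)

#' Delta-method standard error of the age estimate
#'
#' First-order propagation of the uncertainty of both rho and the mutation
#' rate through the ratio `rho/mu`, treating the two as independent:
#' `sqrt(ese_rho^2/mu^2 + rho^2 * se_mu^2 / mu^4)`.  With `se_mu = 0` it
#' reduces to `ese_rho/mu`.
#'
#' @param rho The rho statistic (mutations).
#' @param ese_rho Estimated standard error of rho (mutations).
#' @param mu Mutation rate per lineage per generation; positive.
#' @param se_mu Standard error of `mu`; non-negative.
#' @return Standard error of the age estimate, in generations.
#' @examples
#' age_se_delta(1, 0.790569, mu = 0.01, se_mu = 0.001)
#' @export
age_se_delta <- function(rho, ese_rho, mu, se_mu) {
  if (!is.numeric(mu) || any(mu <= 0)) abort("mu must be positive")
  if (any(se_mu < 0)) abort("se_mu must be non-negative")
  sqrt(ese_rho^2 / mu^2 + rho^2 * se_mu^2 / mu^4)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
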