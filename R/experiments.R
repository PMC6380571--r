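# The two simulation experiments: bias of rho/mu against the true TMRCA,
# and Wald confidence-interval coverage as a function of theta for the
# three standard-error estimators.

#' Least-squares regression through the origin
#'
#' Fits `y = slope * x` by least squares: `slope = sum(x*y)/sum(x^2)` with
#' `slope_se = sqrt(sum((y - slope*x)^2) / ((length(x)-1) * sum(x^2)))`.
#'
#' @param x,y Numeric vectors of equal length >= 2; `sum(x^2)` must be
#'   positive.
#' @return A one-row tibble with `slope` and `slope_se`.
#' @examples
#' regression_through_origin(c(1, 2), c(1, 1)) # slope 3/5
#' @export
regression_through_origin <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    abort("x and y must have equal length of at least 2")
  }
  sxx <- sum(x^2)
  if (sxx == 0) abort("all x are zero: the slope through the origin is undefined")
  slope <- sum(x * y) / sxx
  se <- sqrt(sum((y - slope * x)^2) / ((length(x) - 1) * sxx))
  tibble::tibble(slope = slope, slope_se = se)
}

# One coalescent replicate at (n, N, mu): simulate, drop mutations, and
# return the quantities the experiments need as a plain numeric vector.
.replicate_record <- function(n, N, mu, z) {
  g <- simulate_genealogy(n, N)
  t_true <- .check_ultrametric(g)
  g <- drop_mutations(g, mu)
  s <- .rho_stats(g)
  # mu = 0 is the degenerate no-mutation run: rho = 0 and the age estimate
  # and its interval collapse to 0 rather than 0/0
  inv_mu <- if (mu > 0) 1 / mu else 0
  t_hat <- s["rho"] * inv_mu
  lo <- (s["rho"] - z * s[c("ese_saillard", "ese_cox", "ese_lower")]) * inv_mu
  hi <- (s["rho"] + z * s[c("ese_saillard", "ese_cox", "ese_lower")]) * inv_mu
  c(
    t_true = t_true, rho = unname(s["rho"]), t_hat = unname(t_hat),
    ese_saillard = unname(s["ese_saillard"]),
    ese_cox = unname(s["ese_cox"]),
    ese_lower = unname(s["ese_lower"]),
    hit_saillard = as.numeric(t_true >= lo[1] && t_true <= hi[1]),
    hit_cox = as.numeric(t_true >= lo[2] && t_true <= hi[2]),
    hit_lower = as.numeric(t_true >= lo[3] && t_true <= hi[3])
  )
}

# Run `reps` replicates under order-independent per-replicate seeds and
# return them as a tibble of SimulationRecords.
.run_replicates <- function(n, N, mu, reps, seed, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  seeds <- .replicate_seeds(seed, reps)
  rec <- matrix(0, nrow = reps, ncol = 9L)
  for (i in seq_len(reps)) {
    set.seed(seeds[i])
    rec[i, ] <- .replicate_record(n, N, mu, z)
  }
  colnames(rec) <- c(
    "t_true", "rho", "t_hat", "ese_saillard", "ese_cox", "ese_lower",
    "hit_saillard", "hit_cox", "hit_lower"
  )
  out <- tibble::as_tibble(as.data.frame(rec))
  out$replicate <- seq_len(reps)
  dplyr::relocate(out, "replicate")
}

#' Bias experiment: rho/mu against the true TMRCA
#'
#' Simulates `reps` constant-size coalescent genealogies, drops
#' infinite-sites mutations at rate `mu`, estimates each TMRCA as `rho/mu`,
#' and summarises the signed error and the least-squares regression of the
#' estimate on the truth through the origin.  Under the defaults this is
#' the reference study conditions: N = 1000, n = 100, mu = 0.00234 (theta = 4.68),
#' 10,000 replicates.
#'
#' @param config A [coalescent_config()]; its `seed` drives all randomness.
#' @param level Confidence level used for the recorded Wald intervals.
#' @return An object of class `bias_result` with fields `records` (a tibble
#'   of per-replicate `t_true`, `rho`, `t_hat`, e.s.e.s and CI hits),
#'   `bias` = mean(t_hat - t_true) in generations, `slope`, `slope_se`,
#'   and `config`.  [tidy()] returns the records, [glance()] the one-row
#'   summary, [autoplot()] the estimated-vs-true scatterplot.
#' @export
run_bias_experiment <- function(config = coalescent_config(),
                                level = 0.95) {
  stopifnot(inherits(config, "coalescent_config"))
  rec <- .run_replicates(config$n, config$N, config$mu, config$reps,
                         config$seed, level)
  fit <- regression_through_origin(rec$t_true, rec$t_hat)
  structure(
    list(
      records = rec,
      bias = mean(rec$t_hat - rec$t_true),
      slope = fit$slope,
      slope_se = fit$slope_se,
      level = level,
      config = config
    ),
    class = "bias_result"
  )
}

#' @export
print.bias_result <- function(x, ...) {
  ci <- x$slope + c(-1, 1) * qnorm(0.975) * x$slope_se
  cat(sprintf(
    paste0(
      "<bias_result> %d replicates (n = %d, N = %g, mu = %g, theta = %g)\n",
      "  mean(t_hat - t_true)  %.4g generations\n",
      "  origin slope          %.6g (95%% CI %.6g..%.6g)\n"
    ),
    x$config$reps, x$config$n, x$config$N, x$config$mu, x$config$theta,
    x$bias, x$slope, ci[1], ci[2]
  ))
  invisible(x)
}

#' @rdname run_bias_experiment
#' @param x A `bias_result`.
#' @param ... Unused.
#' @method glance bias_result
#' @export
glance.bias_result <- function(x, ...) {
  tibble::tibble(
    reps = x$config$reps, n = x$config$n, N = x$config$N,
    mu = x$config$mu, theta = x$config$theta,
    bias = x$bias, slope = x$slope, slope_se = x$slope_se,
    mean_t_true = mean(x$records$t_true)
  )
}

#' @rdname run_bias_experiment
#' @method tidy bias_result
#' @export
tidy.bias_result <- function(x, ...) x$records

#' @rdname run_bias_experiment
#' @param object A `bias_result`.
#' @method autoplot bias_result
#' @export
autoplot.bias_result <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$t_true, y = .data$t_hat)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_abline(slope = object$slope, intercept = 0,
                         colour = "black", linetype = "dashed") +
    ggplot2::labs(
      x = "true TMRCA (generations)",
      y = expression(hat(T) == rho / mu ~ "(generations)"),
      title = sprintf("rho/mu vs truth, %d coalescent replicates",
                      object$config$reps),
      subtitle = "red: equality; dashed: least-squares line through the origin"
    )
}

#' Coverage experiment: Wald intervals across a theta grid
#'
#' For each value of theta, runs matched coalescent replicates (same trees
#' and mutations for all three interval flavours) with `mu = theta/(2N)`,
#' and records the fraction of replicates whose Wald interval
#' `(rho +/- z e.s.e.)/mu` (no zero clamp) contains the true TMRCA, for the
#' Saillard, Cox-reconstruction and lower-bound standard errors.  Because
#' the three intervals are nested around the same centre, coverage is
#' ordered lower <= cox <= saillard replicate-by-replicate, hence in
#' aggregate.
#'
#' @param theta Numeric grid of theta values (> 0).  The default
#'   `c(0.5, 1, 2, 5, 10, 20, 50)` spans the transition near theta ~ 10.
#' @param n,N Haploid sample and population size, fixed across the grid.
#' @param reps Replicates per theta value.
#' @param level Nominal confidence level.
#' @param seed Master seed.
#' @return An object of class `coverage_result`; [tidy()] returns the
#'   table with one row per theta (`coverage_saillard`, `coverage_cox`,
#'   `coverage_lower`), [autoplot()] the coverage-vs-theta curves.
#' @export
run_coverage_experiment <- function(theta = c(0.5, 1, 2, 5, 10, 20, 50),
                                    n = 100, N = 1000, reps = 10000,
                                    level = 0.95, seed = 1) {
  if (length(theta) == 0L) abort("theta grid must not be empty")
  if (any(theta <= 0)) abort("all theta values must be positive")
  seeds <- .replicate_seeds(seed, length(theta))
  rows <- lapply(seq_along(theta), function(i) {
    mu <- theta[i] / (2 * N)
    rec <- .run_replicates(n, N, mu, reps, seeds[i], level)
    tibble::tibble(
      theta = theta[i], n = as.integer(n), N = N, mu = mu,
      reps = as.integer(reps),
      coverage_saillard = mean(rec$hit_saillard),
      coverage_cox = mean(rec$hit_cox),
      coverage_lower = mean(rec$hit_lower)
    )
  })
  structure(
    list(table = dplyr::bind_rows(rows), level = level, seed = seed),
    class = "coverage_result"
  )
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("<coverage_result> nominal level %g%%\n", 100 * x$level))
  print(x$table)
  invisible(x)
}

#' @rdname run_coverage_experiment
#' @param x A `coverage_result`.
#' @param ... Unused.
#' @method tidy coverage_result
#' @export
tidy.coverage_result <- function(x, ...) x$table

#' @rdname run_coverage_experiment
#' @method glance coverage_result
#' @export
glance.coverage_result <- function(x, ...) {
  tibble::tibble(
    n_theta = nrow(x$table), level = x$level,
    reps = x$table$reps[1], n = x$table$n[1], N = x$table$N[1]
  )
}

#' @rdname run_coverage_experiment
#' @param object A `coverage_result`.
#' @method autoplot coverage_result
#' @export
autoplot.coverage_result <- function(object, ...) {
  tab <- object$table
  long <- tibble::tibble(
    theta = rep(tab$theta, 3L),
    method = rep(c("saillard", "cox", "lower"), each = nrow(tab)),
    coverage = c(tab$coverage_saillard, tab$coverage_cox,
                 tab$coverage_lower)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$theta, y = .data$coverage,
                                     colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$level, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = expression(theta == 2 * N * mu),
      y = "empirical coverage of the Wald interval",
      colour = "e.s.e."
    )
}
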