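#' Posterior summary of population and individual preferences
#'
#' Posterior means and equal-tail credible intervals for the population mean
#' preference vector q and the concentration w, plus per-individual
#' posterior mean preferences, computed from the stored draws.
#'
#' @param chain a `posterior_chain`.
#' @param ci_level credible level (default 0.95); intervals are equal-tail
#'   empirical quantile intervals.
#' @param hpd if `TRUE`, report highest-posterior-density intervals (shortest
#'   interval containing `ci_level` of the sorted draws) instead of
#'   equal-tail quantiles.
#' @return object of class `preference_summary` with elements
#'   `post_mean_q`, `ci_lower`, `ci_upper`, `post_mean_w`, `w_ci`,
#'   `per_individual_means`, `ci_level`.
#' @export
summarize_chain <- function(chain, ci_level = 0.95, hpd = FALSE) {
  stopifnot(inherits(chain, "posterior_chain"))
  if (n_draws(chain) == 0L) stop("empty chain")
  if (ci_level <= 0 || ci_level >= 1) stop("'ci_level' must be in (0, 1)")
  ci_fun <- if (hpd) hpd_interval else function(v, level) {
    a <- (1 - level) / 2
    unname(quantile(v, c(a, 1 - a)))
  }
  qi <- apply(chain$q, 2L, ci_fun, level = ci_level)
  structure(list(
    post_mean_q = colMeans(chain$q),
    ci_lower = qi[1L, ], ci_upper = qi[2L, ],
    post_mean_w = mean(chain$w),
    w_ci = ci_fun(chain$w, ci_level),
    per_individual_means = apply(chain$p, c(2L, 3L), mean),
    ci_level = ci_level,
    choice_labels = chain$choice_labels,
    population = chain$population
  ), class = "preference_summary")
}

# shortest interval covering `level` of the sorted draws
hpd_interval <- function(v, level) {
  v <- sort(v)
  n <- length(v)
  m <- max(1L, ceiling(level * n))
  if (m >= n) return(c(v[1L], v[n]))
  widths <- v[(m + 1L):n] - v[1L:(n - m)]
  i <- which.min(widths)
  c(v[i], v[i + m])
}

#' @export
print.preference_summary <- function(x, digits = 2, ...) {
  cat(sprintf("Population preference (posterior mean and %d%% CI):\n",
              round(100 * x$ci_level)))
  labs <- if (is.null(x$choice_labels)) {
    paste0("choice", seq_along(x$post_mean_q))
  } else x$choice_labels
  for (k in seq_along(x$post_mean_q)) {
    cat(sprintf("  %-12s %.*f (%.*f, %.*f)\n", labs[k],
                digits, x$post_mean_q[k], digits, x$ci_lower[k],
                digits, x$ci_upper[k]))
  }
  cat(sprintf("Concentration w: %.*f (%.*f, %.*f)\n", digits, x$post_mean_w,
              digits, x$w_ci[1L], digits, x$w_ci[2L]))
  invisible(x)
}

#' Pairwise exceedance probabilities among choices
#'
#' For each ordered pair (a, b), the fraction of stored draws in which the
#' population mean preference for a strictly exceeds that for b.  This is
#' the posterior probability that choice a is preferred over choice b, and
#' `1 - prob_greater[a, b]` is the probability that preference for b is
#' greater than or equal to preference for a.  Exactly tied draws (a
#' measure-zero event for a continuous sampler) are counted to neither
#' side; the diagonal is 0 by convention.  No multiplicity adjustment is
#' applied across the K(K-1)/2 pairs.
#'
#' @param chain a `posterior_chain`.
#' @return a K x K matrix of class `pairwise_report`.
#' @export
pairwise_probabilities <- function(chain) {
  stopifnot(inherits(chain, "posterior_chain"))
  S <- n_draws(chain)
  if (S == 0L) stop("empty chain")
  K <- ncol(chain$q)
  pg <- matrix(0, K, K, dimnames = list(chain$choice_labels, chain$choice_labels))
  for (a in seq_len(K)) {
    for (b in seq_len(K)) {
      if (a != b) pg[a, b] <- mean(chain$q[, a] > chain$q[, b])
    }
  }
  structure(pg, class = c("pairwise_report", "matrix", "array"))
}

#' @export
print.pairwise_report <- function(x, digits = 3, ...) {
  cat("P(row choice preferred over column choice):\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Posterior summary of among-individual variation
#'
#' Summarizes the concentration parameter w of the population Dirichlet,
#' which is inversely proportional to the among-individual variance of
#' preferences: large w means homogeneous individuals clustered at the
#' population mean, small w means polarized individuals near the simplex
#' corners.
#'
#' @param chain a `posterior_chain`.
#' @param ci_level credible level for the equal-tail interval.
#' @param grid_n number of points in the returned density grid.
#' @return list with `mean`, `ci`, and a `density` data frame (grid of w
#'   values and estimated posterior density).
#' @export
individual_variation <- function(chain, ci_level = 0.95, grid_n = 512) {
  stopifnot(inherits(chain, "posterior_chain"))
  if (n_draws(chain) == 0L) stop("empty chain")
  a <- (1 - ci_level) / 2
  ci <- unname(quantile(chain$w, c(a, 1 - a)))
  dens <- if (stats::var(chain$w) > 0) {
    d <- stats::density(chain$w, n = grid_n, from = max(0, min(chain$w) - 1),
                        to = max(chain$w) + 1)
    data.frame(w = d$x, density = d$y)
  } else {
    data.frame(w = chain$w[1L], density = Inf)
  }
  list(mean = mean(chain$w), ci = ci, density = dens)
}
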