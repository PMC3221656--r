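#' Log-likelihood of one replicate's counts
#'
#' Multinomial log-probability of a single count row given that replicate's
#' preference vector, including the multinomial coefficient.  The
#' coefficient cancels in MCMC acceptance ratios but is kept so that
#' deviances (and hence DIC values) are comparable across implementations.
#'
#' @param x_row non-negative integer vector of counts, length K.
#' @param p_row preference probabilities on the open simplex, length K.
#' @return log-density (natural log scale).
#' @export
multinomial_loglik <- function(x_row, p_row) {
  if (length(x_row) != length(p_row)) stop("'x_row' and 'p_row' lengths differ")
  if (any(x_row < 0) || any(x_row != round(x_row))) {
    stop("'x_row' must contain non-negative integers")
  }
  n <- sum(x_row)
  if (n == 0) return(0)
  lgamma(n + 1) - sum(lgamma(x_row + 1)) + sum(x_row * log(p_row))
}

#' Total log-likelihood of a count table
#'
#' Sum of per-replicate multinomial log-likelihoods: the first level of the
#' hierarchical model, a product of J independent multinomials.
#'
#' @param table a [count_table()].
#' @param prefs J x K matrix of individual preferences (rows on the open
#'   simplex); an [individual_prefs()] object or plain matrix.
#' @return log-likelihood.
#' @export
total_loglik <- function(table, prefs) {
  x <- unclass(table)
  p <- unclass(prefs)
  if (!all(dim(x) == dim(p))) stop("count table and preference matrix dimensions differ")
  n <- rowSums(x)
  sum(lgamma(n + 1)) - sum(lgamma(x + 1)) + sum(x * log(p))
}

#' Dirichlet log-density
#'
#' @param p_row point on the open simplex, length K.
#' @param alpha positive Dirichlet parameters, length K.
#' @return log-density; `-Inf` for boundary points (any `p_row` entry 0)
#'   when the corresponding `alpha >= 1`.
#' @export
dirichlet_logpdf <- function(p_row, alpha) {
  if (length(p_row) != length(alpha)) stop("'p_row' and 'alpha' lengths differ")
  if (any(alpha <= 0)) stop("'alpha' entries must be positive")
  if (abs(sum(p_row) - 1) > 1e-8) stop("'p_row' must sum to 1")
  if (any(p_row == 0)) {
    if (any(alpha[p_row == 0] < 1)) return(Inf)
    if (all(alpha[p_row == 0] == 1)) {
      return(lgamma(sum(alpha)) - sum(lgamma(alpha)) +
               sum((alpha - 1) * log(pmax(p_row, 1))))
    }
    return(-Inf)
  }
  lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * log(p_row))
}

#' Conditional prior log-density of individual preferences
#'
#' Each replicate's preference vector is an independent draw from the
#' population-level Dirichlet(w * q); this returns the summed log-density
#' over all replicates.
#'
#' @param prefs J x K preference matrix (rows on the open simplex).
#' @param pop a [pop_params()] object (or list with `q`, `w`).
#' @return log-density.
#' @export
conditional_prior_loglik <- function(prefs, pop) {
  p <- unclass(prefs)
  alpha <- pop$w * pop$q
  if (ncol(p) != length(alpha)) stop("dimension mismatch between prefs and pop params")
  J <- nrow(p)
  J * (lgamma(sum(alpha)) - sum(lgamma(alpha))) +
    sum((alpha - 1) * colSums(log(p)))
}

#' Joint log-posterior (up to the normalizing constant)
#'
#' Likelihood times conditional prior times the hyperpriors on q
#' (Dirichlet) and w (uniform on (0, u)); all on the log scale.
#'
#' @param table a [count_table()].
#' @param prefs J x K preference matrix.
#' @param pop a [pop_params()] object.
#' @param prior a [prior_config()] object.
#' @return log-posterior; `-Inf` when `w >= w_upper`.
#' @export
log_posterior <- function(table, prefs, pop, prior) {
  if (pop$w >= prior$w_upper || pop$w <= 0) return(-Inf)
  total_loglik(table, prefs) +
    conditional_prior_loglik(prefs, pop) +
    dirichlet_logpdf(pop$q, prior$q_prior_alpha) -
    log(prior$w_upper)
}

#' Model deviance
#'
#' Minus twice the log of (likelihood x conditional prior) — the focused
#' deviance used for DIC, which excludes the hyperpriors on q and w.  It can
#' be negative: the conditional prior is a density and exceeds 1 for
#' concentrated populations (large w).
#'
#' @inheritParams log_posterior
#' @return deviance (a real number, possibly negative).
#' @export
model_deviance <- function(table, prefs, pop) {
  -2 * (total_loglik(table, prefs) + conditional_prior_loglik(prefs, pop))
}
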