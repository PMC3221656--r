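# Shared fixtures and independent oracles used across test files.

# random count table drawn from the current RNG stream
random_table <- function(J = 5, K = 3, lambda = 6) {
  suppressWarnings(count_table(matrix(rpois(J * K, lambda), J, K)))
}

# random interior simplex matrix
random_prefs <- function(J, K) {
  g <- matrix(rgamma(J * K, shape = 1), J, K)
  individual_prefs(g / rowSums(g))
}

# hand-build a posterior_chain from explicit draws (S x K q, length-S w,
# S x J x K p); used to test summaries and DIC on known inputs
fake_chain <- function(q, w, p = NULL, constrain_q = FALSE) {
  q <- as.matrix(q)
  S <- nrow(q)
  if (is.null(p)) {
    p <- array(rep(t(q), each = 1), c(S, 1, ncol(q)))
    for (s in seq_len(S)) p[s, 1, ] <- q[s, ]
  }
  structure(list(q = q, w = w, p = p, deviance = NULL,
                 accept = c(q = NA_real_, w = NA_real_),
                 config = NULL, prior = NULL, constrain_q = constrain_q,
                 replicate_labels = NULL, choice_labels = colnames(q),
                 population = "fake"),
            class = "posterior_chain")
}

# posterior mean of q1 for a K = 2 table by deterministic quadrature on the
# analytic marginal: integrating the preference rows out of the
# multinomial x Dirichlet hierarchy leaves a product of Dirichlet-multinomial
# (here beta-binomial) terms in (q, w) only
betabin_posterior_mean_q1 <- function(x, w_upper = 1000,
                                      nq = 400, nw = 400) {
  q1g <- seq(1 / (2 * nq), 1 - 1 / (2 * nq), length.out = nq)
  wg <- exp(seq(log(1e-3), log(w_upper), length.out = nw))
  lp <- outer(q1g, wg, function(q1, w) {
    out <- 0
    for (j in seq_len(nrow(x))) {
      n <- sum(x[j, ])
      out <- out + lgamma(w) - lgamma(n + w) +
        lgamma(x[j, 1] + w * q1) - lgamma(w * q1) +
        lgamma(x[j, 2] + w * (1 - q1)) - lgamma(w * (1 - q1))
    }
    out
  })
  post <- exp(lp - max(lp)) * rep(wg, each = nq)  # Jacobian of the log-w grid
  sum(q1g * rowSums(post)) / sum(post)
}

# Geweke-style z-score comparing first and last segments of a trace, with
# batch-means standard errors to absorb autocorrelation
geweke_z <- function(trace, frac1 = 0.1, frac2 = 0.5, n_batch = 20) {
  n <- length(trace)
  seg1 <- trace[seq_len(floor(frac1 * n))]
  seg2 <- trace[seq.int(n - floor(frac2 * n) + 1L, n)]
  bm <- function(v) {
    b <- matrix(v[seq_len(n_batch * (length(v) %/% n_batch))], ncol = n_batch)
    mu <- colMeans(b)
    list(mean = mean(mu), se = sd(mu) / sqrt(n_batch))
  }
  a <- bm(seg1); b <- bm(seg2)
  (a$mean - b$mean) / sqrt(a$se^2 + b$se^2)
}
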