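test_that("multinomial log-likelihood matches closed forms and dmultinom", {
  expect_equal(multinomial_loglik(c(1, 1), c(0.5, 0.5)), log(0.5))
  expect_equal(multinomial_loglik(c(0, 0, 0), c(0.2, 0.3, 0.5)), 0)
  expect_equal(multinomial_loglik(c(3, 2, 0), c(0.5, 0.3, 0.2)),
               dmultinom(c(3, 2, 0), prob = c(0.5, 0.3, 0.2), log = TRUE))
  expect_error(multinomial_loglik(c(1, 1), c(0.5, 0.3, 0.2)), "lengths differ")
  expect_error(multinomial_loglik(c(1.5, 1), c(0.5, 0.5)), "integers")
})

test_that("exp(multinomial_loglik) sums to 1 over all outcomes with fixed n", {
  p <- c(0.5, 0.3, 0.2)
  for (n in c(2, 4, 6)) {
    grid <- expand.grid(x1 = 0:n, x2 = 0:n)
    grid <- grid[grid$x1 + grid$x2 <= n, ]
    tot <- sum(apply(grid, 1L, function(g) {
      exp(multinomial_loglik(c(g[1], g[2], n - g[1] - g[2]), p))
    }))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("dirichlet_logpdf matches closed forms and integrates to 1", {
  p <- c(0.2, 0.5, 0.3)
  expect_equal(dirichlet_logpdf(p, c(1, 1, 1)), log(2))
  expect_equal(dirichlet_logpdf(c(0.5, 0.5), c(2, 2)), log(1.5))
  expect_equal(dirichlet_logpdf(c(0.3, 0.7), c(2.5, 1.7)),
               dbeta(0.3, 2.5, 1.7, log = TRUE))
  # K = 2: quadrature over the unit interval
  a <- c(1.7, 2.9)
  int <- integrate(function(u) {
    vapply(u, function(v) exp(dirichlet_logpdf(c(v, 1 - v), a)), numeric(1))
  }, 0, 1, rel.tol = 1e-9)
  expect_equal(int$value, 1, tolerance = 1e-6)
  # K = 3: nested quadrature over the triangle x + y <= 1
  a3 <- c(2.2, 1.4, 3.1)
  inner <- function(x) {
    vapply(x, function(xi) {
      integrate(function(y) {
        vapply(y, function(yi) {
          exp(dirichlet_logpdf(c(xi, yi, 1 - xi - yi), a3))
        }, numeric(1))
      }, 0, 1 - xi, rel.tol = 1e-10)$value
    }, numeric(1))
  }
  int3 <- integrate(inner, 0, 1, rel.tol = 1e-9)
  expect_equal(int3$value, 1, tolerance = 1e-6)
})

test_that("conditional prior is the per-row Dirichlet sum", {
  set.seed(21)
  prefs <- random_prefs(6, 3)
  pop <- pop_params(c(0.5, 0.3, 0.2), 7)
  by_row <- sum(apply(prefs, 1L, dirichlet_logpdf, alpha = pop$alpha))
  expect_equal(conditional_prior_loglik(prefs, pop), by_row)
  # flat population: J * log Gamma(K)
  flat <- pop_params(rep(1 / 3, 3), 3)
  expect_equal(conditional_prior_loglik(prefs, flat), 6 * lgamma(3))
  expect_equal(conditional_prior_loglik(prefs[1, , drop = FALSE], pop),
               dirichlet_logpdf(prefs[1, ], pop$alpha))
})

test_that("total log-likelihood is additive over replicates", {
  set.seed(22)
  tab <- random_table(5, 3)
  prefs <- random_prefs(5, 3)
  by_row <- sum(vapply(1:5, function(j) multinomial_loglik(tab[j, ], prefs[j, ]),
                       numeric(1)))
  expect_equal(total_loglik(tab, prefs), by_row)
  # duplicating a replicate doubles the log-likelihood
  tab2 <- suppressWarnings(count_table(rbind(unclass(tab), unclass(tab))))
  prefs2 <- individual_prefs(rbind(unclass(prefs), unclass(prefs)))
  expect_equal(total_loglik(tab2, prefs2), 2 * total_loglik(tab, prefs))
})

test_that("log-posterior decomposes term by term and respects the w bound", {
  set.seed(23)
  tab <- random_table(4, 3)
  prefs <- random_prefs(4, 3)
  pop <- pop_params(c(0.4, 0.35, 0.25), 6)
  prior <- prior_config(3, w_upper = 50)
  expect_equal(log_posterior(tab, prefs, pop, prior),
               total_loglik(tab, prefs) + conditional_prior_loglik(prefs, pop) +
                 dirichlet_logpdf(pop$q, prior$q_prior_alpha) - log(50))
  # flat q prior contributes log Gamma(K) = log 2 for K = 3
  expect_equal(log_posterior(tab, prefs, pop, prior_config(3, w_upper = 50)),
               total_loglik(tab, prefs) + conditional_prior_loglik(prefs, pop) +
                 log(2) - log(50))
  expect_identical(log_posterior(tab, prefs, pop_params(pop$q, 50), prior), -Inf)
  expect_identical(log_posterior(tab, prefs, pop_params(pop$q, 51), prior), -Inf)
})

test_that("log-posterior is invariant under simultaneous column relabeling", {
  set.seed(24)
  tab <- random_table(5, 4)
  prefs <- random_prefs(5, 4)
  q <- c(0.4, 0.3, 0.2, 0.1)
  prior <- prior_config(4)
  perm <- c(3, 1, 4, 2)
  tab_p <- suppressWarnings(count_table(unclass(tab)[, perm]))
  base <- log_posterior(tab, prefs, pop_params(q, 5), prior)
  permuted <- log_posterior(tab_p, individual_prefs(unclass(prefs)[, perm]),
                            pop_params(q[perm], 5), prior)
  expect_equal(base, permuted)
})

test_that("deviance is -2(loglik + conditional prior), hyperpriors excluded", {
  tab1 <- suppressWarnings(count_table(rbind(c(0, 0))))
  expect_equal(model_deviance(tab1, individual_prefs(rbind(c(0.5, 0.5))),
                              pop_params(c(0.5, 0.5), 2)), 0)
  set.seed(25)
  tab <- random_table(5, 3)
  prefs <- random_prefs(5, 3)
  pop <- pop_params(c(0.5, 0.3, 0.2), 9)
  expect_equal(model_deviance(tab, prefs, pop),
               -2 * (total_loglik(tab, prefs) + conditional_prior_loglik(prefs, pop)))
  # concentrated preferences under large w: conditional prior density >> 1,
  # so the deviance goes negative
  tight <- individual_prefs(matrix(rep(c(0.5, 0.3, 0.2), each = 5), 5, 3))
  expect_lt(model_deviance(tab, tight, pop_params(c(0.5, 0.3, 0.2), 5000)), 0)
})

test_that("K = 2 densities coincide with the beta-binomial formulation", {
  set.seed(26)
  x <- rbind(c(4, 2), c(0, 7), c(3, 3))
  tab <- suppressWarnings(count_table(x))
  p1 <- c(0.55, 0.2, 0.48)
  prefs <- individual_prefs(cbind(p1, 1 - p1))
  expect_equal(total_loglik(tab, prefs),
               sum(dbinom(x[, 1], rowSums(x), p1, log = TRUE)))
  pop <- pop_params(c(0.45, 0.55), 8)
  expect_equal(conditional_prior_loglik(prefs, pop),
               sum(dbeta(p1, 8 * 0.45, 8 * 0.55, log = TRUE)))
})
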