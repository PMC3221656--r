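test_that("chains are bit-reproducible given a seed", {
  set.seed(1)
  tab <- random_table(6, 3)
  cfg <- mcmc_config(n_steps = 300, burnin = 50, seed = 42)
  ch1 <- run_chain(tab, config = cfg)
  ch2 <- run_chain(tab, config = cfg)
  expect_identical(ch1$q, ch2$q)
  expect_identical(ch1$w, ch2$w)
  expect_identical(ch1$p, ch2$p)
})

test_that("config and chain invariants hold", {
  expect_error(mcmc_config(n_steps = 100, thin = 200))
  set.seed(2)
  tab <- random_table(4, 3)
  ch <- run_chain(tab, config = mcmc_config(n_steps = 1000, burnin = 100,
                                            thin = 3, seed = 1))
  expect_equal(n_draws(ch), 1000 %/% 3)
  expect_true(all(abs(rowSums(ch$q) - 1) < 1e-10))
  expect_true(all(ch$w > 0 & ch$w < 1000))
  expect_true(all(abs(apply(ch$p, c(1, 2), sum) - 1) < 1e-10))
})

test_that("individual Gibbs update draws from the conjugate Dirichlet posterior", {
  # K = 2, x = (2, 1), w*q = (1, 1): the full conditional is Beta(3, 2)
  set.seed(3)
  n <- 20000
  tab <- count_table(matrix(rep(c(2L, 1L), each = n), n, 2))
  draws <- gibbs_update_individuals(tab, pop_params(c(0.5, 0.5), 2))[, 1]
  expect_gt(suppressWarnings(ks.test(draws, pbeta, 3, 2))$p.value, 0.01)
  # moment formula: E[p_k] = (x_k + w q_k) / (n + w), 3-SE band
  pop <- pop_params(c(0.3, 0.7), 5)
  tab2 <- count_table(matrix(rep(c(4L, 2L), each = n), n, 2))
  d2 <- gibbs_update_individuals(tab2, pop)[, 1]
  mu <- (4 + 5 * 0.3) / (6 + 5)
  expect_lt(abs(mean(d2) - mu), 3 * sd(d2) / sqrt(n))
  # no data: the draw is from the conditional prior Dirichlet(w q)
  tab0 <- suppressWarnings(count_table(matrix(0L, n, 2)))
  d0 <- gibbs_update_individuals(tab0, pop_params(c(0.5, 0.5), 4))[, 1]
  expect_gt(suppressWarnings(ks.test(d0, pbeta, 2, 2))$p.value, 0.01)
})

test_that("MH updates accept identical proposals and reject out-of-support w", {
  set.seed(4)
  prefs <- random_prefs(5, 3)
  prior <- prior_config(3, w_upper = 100)
  pop <- pop_params(c(0.4, 0.4, 0.2), 6)
  for (i in 1:20) {
    upd <- mh_update_q(pop, prefs, prior, proposal = pop$q)
    expect_true(attr(upd, "accepted"))
    updw <- mh_update_w(pop, prefs, prior, proposal = pop$w)
    expect_true(attr(updw, "accepted"))
    rej <- mh_update_w(pop, prefs, prior, proposal = 100)
    expect_false(attr(rej, "accepted"))
    expect_equal(rej$w, pop$w)
  }
})

test_that("q sampler concentrates near a common preference vector", {
  set.seed(5)
  v <- c(0.55, 0.3, 0.15)
  prefs <- individual_prefs(matrix(rep(v, each = 200), 200, 3))
  prior <- prior_config(3)
  pop <- pop_params(rep(1 / 3, 3), 50)
  qs <- matrix(NA_real_, 3000, 3)
  for (s in seq_len(3000)) {
    pop <- mh_update_q(pop, prefs, prior, q_scale = 200)
    qs[s, ] <- pop$q
  }
  expect_lt(max(abs(colMeans(qs[1001:3000, ]) - v)), 0.05)
})

test_that("w sampler tracks among-individual dispersion directionally", {
  set.seed(6)
  prior <- prior_config(3)
  run_w <- function(prefs) {
    pop <- pop_params(rep(1 / 3, 3), 3)
    ws <- numeric(2000)
    for (s in seq_len(2000)) {
      pop <- mh_update_w(pop, prefs, prior)
      ws[s] <- pop$w
    }
    mean(ws[501:2000])
  }
  tight <- individual_prefs(matrix(rep(1 / 3, 60), 20, 3) +
                              cbind(e <- runif(20, -0.01, 0.01), -e / 2, -e / 2))
  g <- matrix(rgamma(60, 0.1), 20, 3)
  polarized <- individual_prefs(pmax(g, 1e-12) / rowSums(pmax(g, 1e-12)))
  expect_gt(run_w(tight), 50)
  expect_lt(run_w(polarized), 5)
})

test_that("traces pass a Geweke-style stationarity screen", {
  set.seed(7)
  tab <- generate_dataset(sim_config(seed = 70))
  ch <- run_chain(tab, config = mcmc_config(n_steps = 20000, burnin = 4000,
                                            seed = 71))
  expect_lt(abs(geweke_z(ch$q[, 1])), 3)
  expect_lt(abs(geweke_z(ch$w)), 3)
})

test_that("column relabeling permutes the posterior correspondingly", {
  set.seed(8)
  tab <- generate_dataset(sim_config(pop_q = c(0.6, 0.3, 0.1), pop_w = 10,
                                     seed = 80))
  perm <- c(2, 3, 1)
  tab_p <- suppressWarnings(count_table(unclass(tab)[, perm]))
  cfg <- mcmc_config(n_steps = 8000, burnin = 2000, seed = 81)
  m1 <- colMeans(run_chain(tab, config = cfg)$q)
  m2 <- colMeans(run_chain(tab_p, config = cfg)$q)
  expect_lt(max(abs(m1[perm] - m2)), 0.02)
})

test_that("compiled and pure-R engines agree on the posterior", {
  set.seed(9)
  tab <- generate_dataset(sim_config(n_replicates = 10, seed = 90))
  cfg <- mcmc_config(n_steps = 4000, burnin = 1000, seed = 91)
  m_cpp <- summarize_chain(run_chain(tab, config = cfg, engine = "cpp"))
  m_r <- summarize_chain(run_chain(tab, config = cfg, engine = "r"))
  expect_lt(max(abs(m_cpp$post_mean_q - m_r$post_mean_q)), 0.03)
  expect_lt(abs(log(m_cpp$post_mean_w / m_r$post_mean_w)), 0.4)
})

test_that("K = 2 posterior matches the analytic-marginal quadrature oracle", {
  set.seed(10)
  x <- cbind(c(7L, 2L, 9L, 4L, 1L, 8L, 3L, 6L), c(3L, 8L, 1L, 5L, 9L, 2L, 6L, 4L))
  tab <- count_table(x)
  ch <- run_chain(tab, config = mcmc_config(n_steps = 30000, burnin = 5000,
                                            seed = 100))
  expect_lt(abs(mean(ch$q[, 1]) - betabin_posterior_mean_q1(x)), 0.01)
})

test_that("constrained fits keep q fixed at the uniform vector", {
  set.seed(12)
  tab <- random_table(6, 3)
  ch <- run_chain(tab, config = mcmc_config(n_steps = 500, burnin = 100, seed = 13),
                  constrain_q = TRUE)
  expect_true(all(ch$q == 1 / 3))
  expect_true(is.na(ch$accept["q"]))
  expect_gt(ch$accept["w"], 0)
})

test_that("chain serialization round-trips and counts columns correctly", {
  set.seed(14)
  tab <- random_table(2, 3)
  ch <- run_chain(tab, config = mcmc_config(n_steps = 10, burnin = 5, seed = 15))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_chain(ch, path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 11)  # header + 10 draws
  expect_length(strsplit(body[1], "\t")[[1]], 1 + 2 * 3 + 3 + 1)
  back <- read_chain(path)
  expect_identical(back$q, ch$q)
  expect_identical(back$w, ch$w)
  expect_identical(back$p, ch$p)
  # empty chain refuses to serialize
  ch0 <- ch
  ch0$w <- numeric(0)
  expect_error(write_chain(ch0, path), "empty")
})
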