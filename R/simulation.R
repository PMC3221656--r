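# Synthetic choice-count data: per-replicate totals drawn uniformly on an
# integer range, individual preference vectors drawn from a population-level
# Dirichlet, counts multinomial.  Defaults reproduce the null-calibration
# design: 20 replicates, 3 choices, totals on [5, 40], flat Dirichlet
# population, 1000 datasets.

#' Simulation configuration
#'
#' @param n_replicates replicates (rows) per dataset; default 20.
#' @param n_choices choice categories; default 3.
#' @param total_min,total_max bounds of the per-replicate total count;
#'   default 5 and 40.
#' @param n_datasets number of datasets for calibration runs; default 1000.
#' @param pop_q population mean preference: a simplex vector, or `"uniform"`
#'   for (1/K, ..., 1/K).
#' @param pop_w population concentration: a positive scalar, or `"flat"` for
#'   the flat Dirichlet(1, ..., 1) population (the no-preference null, which
#'   corresponds to uniform q with w = K).
#' @param totals_method `"rounded_uniform"` (default): totals are continuous
#'   Uniform(total_min, total_max) rounded to the nearest integer, so the
#'   endpoints carry half weight; `"discrete_uniform"`: equal weight on
#'   every integer in the range.
#' @param seed integer seed or `NULL`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_replicates = 20, n_choices = 3, total_min = 5,
                       total_max = 40, n_datasets = 1000, pop_q = "uniform",
                       pop_w = "flat",
                       totals_method = c("rounded_uniform", "discrete_uniform"),
                       seed = NULL) {
  stopifnot(n_replicates >= 1, n_choices >= 2, total_min <= total_max,
            total_min >= 0, n_datasets >= 1)
  totals_method <- match.arg(totals_method)
  K <- as.integer(n_choices)
  if (identical(pop_q, "uniform")) pop_q <- rep(1 / K, K)
  if (length(pop_q) != K || abs(sum(pop_q) - 1) > 1e-10 || any(pop_q <= 0)) {
    stop("'pop_q' must be \"uniform\" or a length-K simplex vector")
  }
  if (identical(pop_w, "flat")) pop_w <- K   # Dirichlet(1,...,1) = w*q with w = K, q uniform
  if (!is.numeric(pop_w) || pop_w <= 0) stop("'pop_w' must be \"flat\" or a positive scalar")
  structure(list(n_replicates = as.integer(n_replicates), n_choices = K,
                 total_min = as.integer(total_min),
                 total_max = as.integer(total_max),
                 n_datasets = as.integer(n_datasets),
                 pop_q = as.numeric(pop_q), pop_w = as.numeric(pop_w),
                 totals_method = totals_method, seed = seed),
            class = "sim_config")
}

# Dirichlet draws via normalized gammas, rows of an n x K matrix
rdirichlet_matrix <- function(n, alpha) {
  K <- length(alpha)
  g <- matrix(rgamma(n * K, shape = rep(alpha, each = n)), nrow = n)
  g <- pmax(g, 1e-300)
  g / rowSums(g)
}

#' Generate one synthetic count dataset
#'
#' For each replicate: a total count from the configured uniform range, a
#' preference vector from the population Dirichlet(w * q), and a multinomial
#' count row.  The generating truth is attached for recovery studies.
#'
#' @param config a [sim_config()].
#' @param population label for the generated table.
#' @return a [count_table()] with attribute `truth` (a list holding the
#'   generating `pop` ([pop_params()]) and `prefs` ([individual_prefs()])).
#' @export
generate_dataset <- function(config = sim_config(), population = "sim") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  J <- config$n_replicates; K <- config$n_choices
  tot <- if (config$totals_method == "rounded_uniform") {
    as.integer(round(runif(J, config$total_min, config$total_max)))
  } else {
    as.integer(sample.int(config$total_max - config$total_min + 1L, J,
                          replace = TRUE)) + config$total_min - 1L
  }
  pop <- pop_params(config$pop_q, config$pop_w)
  prefs <- rdirichlet_matrix(J, pop$alpha)
  x <- t(vapply(seq_len(J),
                function(j) drop(rmultinom(1L, tot[j], prefs[j, ])),
                integer(K)))
  tab <- suppressWarnings(count_table(x, population = population))
  attr(tab, "truth") <- list(pop = pop, prefs = individual_prefs(prefs))
  tab
}

#' Null calibration study
#'
#' Generates datasets from the no-preference population (flat Dirichlet) and
#' records, for each dataset, the p-values of the requested classical tests
#' and (optionally) the DIC difference between the constrained and
#' unconstrained hierarchical fits.  The tail summaries are the 5% quantile
#' of each p-value set — near 0.05 when a test is well calibrated — and the
#' 5% and 95% quantiles of delta DIC, whose upper tail is the relevant one
#' for the rate of falsely favoring the unconstrained (preference) model.
#'
#' @param config a [sim_config()]; should describe a flat population.
#' @param tests character subset of `c("friedman", "quade", "anova")`.
#' @param dic if `TRUE`, also fit both hierarchical models per dataset and
#'   record delta DIC = DIC(constrained) - DIC(unconstrained).
#' @param mcmc an [mcmc_config()] for the DIC arm.  The default uses
#'   shortened chains (burnin 2000, 8000 post-burnin steps): thousands of
#'   model fits at full chain length are unnecessary for a tail quantile of
#'   a dataset-level statistic.
#' @param progress print a dot every 50 datasets.
#' @return object of class `calibration_report`: a per-dataset data frame
#'   `values` and a `summary` list of tail quantiles.
#' @export
run_null_calibration <- function(config = sim_config(),
                                 tests = c("friedman", "quade", "anova"),
                                 dic = FALSE,
                                 mcmc = mcmc_config(n_steps = 8000, burnin = 2000),
                                 progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  tests <- match.arg(tests, several.ok = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_datasets
  cols <- c(tests, if (dic) "delta_dic")
  vals <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  cfg1 <- config
  cfg1$seed <- NULL          # one stream for the whole study
  mcmc$seed <- NULL
  for (i in seq_len(n)) {
    tab <- generate_dataset(cfg1)
    if ("friedman" %in% tests) vals[i, "friedman"] <- friedman_test(tab)$p.value
    if ("quade" %in% tests) vals[i, "quade"] <- quade_test(tab)$p.value
    if ("anova" %in% tests) vals[i, "anova"] <- arcsine_anova(tab)$p.value
    if (dic) vals[i, "delta_dic"] <- compare_constrained(tab, config = mcmc)$delta
    if (progress && i %% 50L == 0L) cat(".")
  }
  if (progress) cat("\n")
  summ <- list()
  for (tn in tests) {
    summ[[paste0(tn, "_p05")]] <- unname(quantile(vals[, tn], 0.05))
  }
  if (dic) {
    summ$delta_dic_q05 <- unname(quantile(vals[, "delta_dic"], 0.05))
    summ$delta_dic_q95 <- unname(quantile(vals[, "delta_dic"], 0.95))
  }
  structure(list(values = as.data.frame(vals), summary = summ, config = config),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Null calibration over %d datasets (J=%d, K=%d, totals %d..%d):\n",
              nrow(x$values), x$config$n_replicates, x$config$n_choices,
              x$config$total_min, x$config$total_max))
  for (nm in names(x$summary)) {
    cat(sprintf("  %-16s %.4f\n", nm, x$summary[[nm]]))
  }
  invisible(x)
}

#' Parameter recovery study
#'
#' Repeated simulate-then-fit cycles at a known population truth; reports
#' the bias of the posterior mean and the empirical coverage of equal-tail
#' credible intervals for every q component and for w.
#'
#' @param true_q simplex vector of generating mean preferences.
#' @param true_w generating concentration.
#' @param config a [sim_config()] (its `pop_q`/`pop_w` are overridden by the
#'   explicit truth; `n_datasets` is the number of cycles).
#' @param mcmc an [mcmc_config()] used for every fit.
#' @param ci_level interval level whose coverage is assessed.
#' @param progress print a dot every 10 cycles.
#' @return object of class `recovery_report` with per-cycle posterior means
#'   and interval hits, plus `bias_q`, `coverage_q`, `bias_w`, `coverage_w`.
#' @export
run_recovery_study <- function(true_q, true_w, config = sim_config(n_datasets = 100),
                               mcmc = mcmc_config(n_steps = 8000, burnin = 2000),
                               ci_level = 0.95, progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  true_q <- as.numeric(true_q)
  K <- length(true_q)
  config$pop_q <- true_q
  config$pop_w <- true_w
  config$n_choices <- K
  if (!is.null(config$seed)) set.seed(config$seed)
  config$seed <- NULL
  mcmc$seed <- NULL
  n <- config$n_datasets
  qmean <- matrix(NA_real_, n, K)
  qhit <- matrix(NA, n, K)
  wmean <- numeric(n)
  whit <- logical(n)
  for (i in seq_len(n)) {
    tab <- generate_dataset(config)
    ch <- run_chain(tab, config = mcmc)
    s <- summarize_chain(ch, ci_level = ci_level)
    qmean[i, ] <- s$post_mean_q
    qhit[i, ] <- s$ci_lower <= true_q & true_q <= s$ci_upper
    wmean[i] <- s$post_mean_w
    whit[i] <- s$w_ci[1L] <= true_w && true_w <= s$w_ci[2L]
    if (progress && i %% 10L == 0L) cat(".")
  }
  if (progress) cat("\n")
  structure(list(q_post_means = qmean, q_hits = qhit, w_post_means = wmean,
                 w_hits = whit, true_q = true_q, true_w = true_w,
                 bias_q = colMeans(qmean) - true_q,
                 coverage_q = colMeans(qhit),
                 bias_w = mean(wmean) - true_w,
                 coverage_w = mean(whit), ci_level = ci_level),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery over %d cycles at q = (%s), w = %g:\n",
              nrow(x$q_post_means), paste(x$true_q, collapse = ", "), x$true_w))
  cat("  bias(q):     ", paste(sprintf("%+.4f", x$bias_q), collapse = " "), "\n")
  cat(sprintf("  coverage(q): %s  (nominal %.2f)\n",
              paste(sprintf("%.2f", x$coverage_q), collapse = " "), x$ci_level))
  cat(sprintf("  bias(w): %+.3f   coverage(w): %.2f\n", x$bias_w, x$coverage_w))
  invisible(x)
}
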