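#' MCMC configuration
#'
#' @param n_steps number of post-burnin steps (default 40000).
#' @param burnin number of discarded initial steps (default 10000).
#' @param thin store every `thin`-th post-burnin draw (default 1).
#' @param seed integer seed, or `NULL` to leave the RNG state alone.
#' @param q_proposal_scale concentration `delta` of the Dirichlet proposal
#'   for the population mean: proposals are drawn from
#'   Dirichlet(delta * q_current).  Larger values make smaller moves.
#' @param w_proposal_sd standard deviation of the Gaussian random walk on
#'   log(w).
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_steps = 40000, burnin = 10000, thin = 1,
                        seed = NULL, q_proposal_scale = 100,
                        w_proposal_sd = 0.3) {
  stopifnot(n_steps >= 1, burnin >= 0, thin >= 1, thin <= n_steps,
            q_proposal_scale > 0, w_proposal_sd > 0)
  structure(list(n_steps = as.integer(n_steps), burnin = as.integer(burnin),
                 thin = as.integer(thin), seed = seed,
                 q_proposal_scale = q_proposal_scale,
                 w_proposal_sd = w_proposal_sd),
            class = "mcmc_config")
}

#' Gibbs update of all individual preference rows
#'
#' The multinomial likelihood is conjugate to the Dirichlet conditional
#' prior, so each replicate's preference row has the exact full conditional
#' Dirichlet(x_j + w * q).  This draws all rows at once.
#'
#' @param table a [count_table()].
#' @param pop current [pop_params()].
#' @return an [individual_prefs()] matrix of fresh draws.
#' @export
gibbs_update_individuals <- function(table, pop) {
  x <- unclass(table)
  J <- nrow(x); K <- ncol(x)
  shape <- sweep(x, 2, pop$w * pop$q, `+`)
  g <- matrix(rgamma(J * K, shape = shape), nrow = J, ncol = K)
  g <- pmax(g, 1e-300)
  individual_prefs(g / rowSums(g))
}

#' Metropolis-Hastings update of the population mean preference q
#'
#' Proposes q' ~ Dirichlet(delta * q_current) and accepts with the usual
#' Metropolis-Hastings probability for the full conditional of q (the
#' conditional prior of all preference rows times the Dirichlet hyperprior),
#' including the Hastings correction for the asymmetric proposal.
#'
#' @param pop current [pop_params()].
#' @param prefs current J x K preference matrix.
#' @param prior a [prior_config()].
#' @param q_scale proposal concentration delta.
#' @param proposal optional simplex vector to use as the proposal instead of
#'   drawing one (for testing the acceptance rule).
#' @return a [pop_params()] with attribute `"accepted"` (logical).
#' @export
mh_update_q <- function(pop, prefs, prior, q_scale = 100, proposal = NULL) {
  q <- pop$q; w <- pop$w
  K <- length(q)
  if (is.null(proposal)) {
    g <- pmax(rgamma(K, shape = q_scale * q), 1e-300)
    qp <- g / sum(g)
  } else {
    qp <- proposal
  }
  clp <- colSums(log(unclass(prefs)))
  J <- nrow(prefs)
  target <- function(qv) {
    a <- w * qv
    J * (lgamma(w) - sum(lgamma(a))) + sum((a - 1) * clp) +
      sum((prior$q_prior_alpha - 1) * log(qv))
  }
  lr <- target(qp) - target(q) +
    dirichlet_logpdf(q, q_scale * qp) - dirichlet_logpdf(qp, q_scale * q)
  accepted <- log(runif(1)) < lr
  out <- if (accepted) pop_params(qp, w) else pop
  attr(out, "accepted") <- accepted
  out
}

#' Metropolis-Hastings update of the concentration w
#'
#' Gaussian random walk on log(w) with the Jacobian correction; proposals at
#' or above the uniform prior's upper bound are rejected outright.
#'
#' @inheritParams mh_update_q
#' @param w_sd random-walk standard deviation on the log scale.
#' @param proposal optional positive scalar proposal (for testing).
#' @return a [pop_params()] with attribute `"accepted"`.
#' @export
mh_update_w <- function(pop, prefs, prior, w_sd = 0.3, proposal = NULL) {
  w <- pop$w
  wp <- if (is.null(proposal)) w * exp(rnorm(1, sd = w_sd)) else proposal
  accepted <- FALSE
  if (wp > 0 && wp < prior$w_upper) {
    clp <- colSums(log(unclass(prefs)))
    J <- nrow(prefs)
    cp <- function(wv) {
      a <- wv * pop$q
      J * (lgamma(wv) - sum(lgamma(a))) + sum((a - 1) * clp)
    }
    lr <- cp(wp) - cp(w) + log(wp) - log(w)
    accepted <- log(runif(1)) < lr
  }
  out <- if (accepted) pop_params(pop$q, wp) else pop
  attr(out, "accepted") <- accepted
  out
}

#' Fit the hierarchical model by MCMC
#'
#' Runs the Metropolis-within-Gibbs sampler: an exact conjugate Gibbs draw
#' for every individual preference row, then Metropolis-Hastings updates of
#' the population mean q (skipped in the constrained, equal-preference
#' model, where q is fixed at the uniform vector) and of the concentration
#' w.  Initial values are add-one smoothed count proportions for p, their
#' renormalized mean for q, and w = K.
#'
#' @param table a [count_table()].
#' @param prior a [prior_config()]; defaults to the flat Dirichlet prior on
#'   q and Uniform(0, 1000) on w.
#' @param config an [mcmc_config()].
#' @param constrain_q if `TRUE`, fit the constrained (no-preference) model
#'   with q fixed at (1/K, ..., 1/K); only p and w are updated.
#' @param engine `"cpp"` (compiled sampler, default) or `"r"` (pure-R
#'   reference loop over the exported update functions; much slower, used
#'   for cross-validation).
#' @return object of class `posterior_chain`: stored draws of `q`
#'   (draws x K), `w` (vector), `p` (draws x J x K array), the per-draw
#'   `deviance` trace, acceptance rates, and the run configuration.
#' @examples
#' ct <- count_table(rbind(c(8, 2, 1), c(5, 5, 3), c(9, 1, 2)))
#' ch <- run_chain(ct, config = mcmc_config(n_steps = 500, burnin = 100, seed = 1))
#' summarize_chain(ch)
#' @export
run_chain <- function(table, prior = NULL, config = mcmc_config(),
                      constrain_q = FALSE, engine = c("cpp", "r")) {
  stopifnot(inherits(table, "count_table"))
  engine <- match.arg(engine)
  x <- unclass(table)
  J <- nrow(x); K <- ncol(x)
  if (is.null(prior)) prior <- prior_config(K)
  if (length(prior$q_prior_alpha) != K) {
    stop("prior dimension does not match the number of choices")
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  p0 <- (x + 1) / (rowSums(x) + K)
  q0 <- if (constrain_q) rep(1 / K, K) else {
    m <- colMeans(p0); m / sum(m)
  }
  w0 <- K
  lp0 <- log_posterior(table, individual_prefs(p0), pop_params(q0, w0), prior)
  if (!is.finite(lp0)) {
    stop("log-posterior not finite at the initial state (log_posterior = ",
         lp0, "); check counts and prior configuration")
  }

  if (engine == "cpp") {
    raw <- .run_chain_cpp(x, prior$q_prior_alpha, prior$w_upper,
                          config$burnin, config$n_steps, config$thin,
                          config$q_proposal_scale, config$w_proposal_sd,
                          constrain_q, as.numeric(t(p0)), q0, w0)
    p_arr <- aperm(raw$p, c(3L, 2L, 1L))
    q_draws <- raw$q
    w_draws <- raw$w
    dev <- raw$deviance
    accept <- c(q = raw$accept_q, w = raw$accept_w)
  } else {
    n_store <- config$n_steps %/% config$thin
    q_draws <- matrix(NA_real_, n_store, K)
    w_draws <- dev <- numeric(n_store)
    p_arr <- array(NA_real_, c(n_store, J, K))
    pop <- pop_params(q0, w0)
    acc_q <- acc_w <- 0L
    stored <- 0L
    total <- config$burnin + config$n_steps
    for (step in seq_len(total)) {
      prefs <- gibbs_update_individuals(table, pop)
      if (!constrain_q) {
        pop <- mh_update_q(pop, prefs, prior, config$q_proposal_scale)
        acc_q <- acc_q + attr(pop, "accepted")
      }
      pop <- mh_update_w(pop, prefs, prior, config$w_proposal_sd)
      acc_w <- acc_w + attr(pop, "accepted")
      post <- step - config$burnin
      if (post >= 1L && post %% config$thin == 0L && stored < n_store) {
        stored <- stored + 1L
        q_draws[stored, ] <- pop$q
        w_draws[stored] <- pop$w
        p_arr[stored, , ] <- unclass(prefs)
        dev[stored] <- model_deviance(table, prefs, pop)
      }
    }
    accept <- c(q = if (constrain_q) NA_real_ else acc_q / total,
                w = acc_w / total)
  }

  colnames(q_draws) <- colnames(x)
  structure(list(q = q_draws, w = w_draws, p = p_arr, deviance = dev,
                 accept = accept, config = config, prior = prior,
                 constrain_q = constrain_q,
                 replicate_labels = rownames(x), choice_labels = colnames(x),
                 population = population_label(table)),
            class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(sprintf(
    "posterior_chain: %d stored draws, %d replicates x %d choices (population '%s')\n",
    length(x$w), dim(x$p)[2], dim(x$p)[3], x$population))
  cat(sprintf("  model: %s; acceptance q = %s, w = %.3f\n",
              if (x$constrain_q) "constrained (q fixed uniform)" else "unconstrained",
              ifelse(is.na(x$accept["q"]), "-", sprintf("%.3f", x$accept["q"])),
              x$accept["w"]))
  cat("  posterior mean q:", paste(sprintf("%.3f", colMeans(x$q)), collapse = " "),
      sprintf("; mean w: %.2f\n", mean(x$w)))
  invisible(x)
}

#' Number of stored draws in a chain
#' @param chain a `posterior_chain`.
#' @export
n_draws <- function(chain) length(chain$w)

#' Write a posterior chain to a tab-delimited trace file
#'
#' One row per stored draw; columns are the step index, all individual
#' preference parameters `p[j][k]` in row-major order, the population mean
#' `q[k]`, and the concentration `w`.  Values are written with 17
#' significant digits so that [read_chain()] inverts the file bit-exactly.
#'
#' @param chain a `posterior_chain` with at least one stored draw.
#' @param path output file path.
#' @export
write_chain <- function(chain, path) {
  stopifnot(inherits(chain, "posterior_chain"))
  S <- n_draws(chain)
  if (S == 0L) stop("cannot write an empty chain")
  J <- dim(chain$p)[2]; K <- dim(chain$p)[3]
  pm <- matrix(aperm(chain$p, c(1L, 3L, 2L)), nrow = S)  # columns p[j][k] row-major
  m <- cbind(pm, chain$q, chain$w)
  cols <- c(paste0("p.", rep(seq_len(J), each = K), ".", rep(seq_len(K), J)),
            paste0("q.", seq_len(K)), "w")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# countpref chain: J=%d K=%d draws=%d constrain_q=%s", J, K,
                       S, chain$constrain_q),
               sprintf("# population=%s", chain$population),
               sprintf("# choices=%s", paste(chain$choice_labels, collapse = "\t")),
               sprintf("# replicates=%s", paste(chain$replicate_labels, collapse = "\t")),
               paste(c("step", cols), collapse = "\t")), con)
  body <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(seq_len(S), body, sep = "\t"), con)
  invisible(path)
}

#' Read a posterior chain trace file written by [write_chain()]
#'
#' @param path trace file path.
#' @return a `posterior_chain` (the deviance trace is not stored in the
#'   file; it is recomputed on demand by [compute_dic()]).
#' @export
read_chain <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 4L)
  meta <- regmatches(hdr[1L], gregexpr("[A-Za-z_]+=[^ ]+", hdr[1L]))[[1L]]
  kv <- do.call(rbind, strsplit(meta, "="))
  J <- as.integer(kv[kv[, 1] == "J", 2])
  K <- as.integer(kv[kv[, 1] == "K", 2])
  constrain_q <- as.logical(kv[kv[, 1] == "constrain_q", 2])
  pop <- sub("^# population=", "", hdr[2L])
  choice_labels <- strsplit(sub("^# choices=", "", hdr[3L]), "\t")[[1L]]
  replicate_labels <- strsplit(sub("^# replicates=", "", hdr[4L]), "\t")[[1L]]
  d <- as.matrix(read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                            check.names = FALSE))
  dimnames(d) <- NULL
  S <- nrow(d)
  pm <- d[, 1L + seq_len(J * K), drop = FALSE]
  p_arr <- aperm(array(t(pm), c(K, J, S)), c(3L, 2L, 1L))
  q_draws <- d[, 1L + J * K + seq_len(K), drop = FALSE]
  colnames(q_draws) <- choice_labels
  structure(list(q = q_draws,
                 w = d[, ncol(d)],
                 p = p_arr, deviance = NULL, accept = c(q = NA_real_, w = NA_real_),
                 config = NULL, prior = NULL, constrain_q = constrain_q,
                 replicate_labels = replicate_labels, choice_labels = choice_labels,
                 population = pop),
            class = "posterior_chain")
}
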