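# Conventional comparators for replicated choice counts: Friedman and Quade
# rank tests (blocks = replicates, treatments = choices) and one-way ANOVA on
# arcsine-square-root transformed proportions.  All return standard "htest"
# objects.  Ties are handled by midranks throughout.

#' Friedman rank test on a count table
#'
#' Within-replicate midranks of counts; the tie-corrected Friedman
#' chi-square statistic on K - 1 degrees of freedom (delegates to
#' [stats::friedman.test()]).  A table whose within-replicate rankings carry
#' no information (all counts tied within every replicate) returns statistic
#' 0 and p = 1.
#'
#' @param table a [count_table()].
#' @return an object of class `htest`.
#' @export
friedman_test <- function(table) {
  stopifnot(inherits(table, "count_table"))
  y <- matrix(as.numeric(table), nrow(table), ncol(table))
  if (nrow(y) < 2L) stop("need at least 2 replicates")
  if (all(apply(y, 1L, function(r) length(unique(r)) == 1L))) {
    return(structure(list(statistic = c(`Friedman chi-squared` = 0),
                          parameter = c(df = ncol(y) - 1),
                          p.value = 1, method = "Friedman rank sum test",
                          data.name = "count table"),
                     class = "htest"))
  }
  out <- stats::friedman.test(y)
  out$data.name <- "count table"
  out
}

#' Quade rank test on a count table
#'
#' Within-replicate midranks centered at (K + 1)/2, weighted by a block
#' (replicate) rank and compared by the Quade F statistic on
#' (K - 1, (J - 1)(K - 1)) degrees of freedom.  Two block weightings are
#' available:
#'
#' * `"totals"` (default): blocks are ranked by their total count, so a
#'   replicate contributing 50 observations weighs more than one contributing
#'   10 — the information-weighted variant appropriate for count data, where
#'   replicates differ in how much they tell us.
#' * `"range"`: blocks are ranked by their within-replicate sample range
#'   (the textbook Quade test; delegates to [stats::quade.test()]).
#'
#' @param table a [count_table()].
#' @param weighting block-weight variant, see above.
#' @return an object of class `htest`.
#' @export
quade_test <- function(table, weighting = c("totals", "range")) {
  stopifnot(inherits(table, "count_table"))
  weighting <- match.arg(weighting)
  y <- matrix(as.numeric(table), nrow(table), ncol(table))
  J <- nrow(y); K <- ncol(y)
  if (J < 2L) stop("need at least 2 replicates")
  if (weighting == "range") {
    out <- stats::quade.test(y)
    out$data.name <- "count table"
    return(out)
  }
  r <- t(apply(y, 1L, rank))                 # midranks within replicate
  qwt <- rank(rowSums(y))                    # midranks of replicate totals
  s <- qwt * (r - (K + 1) / 2)
  A <- sum(s^2)
  B <- sum(colSums(s)^2) / J
  if (A <= B + 1e-12) {
    if (A < 1e-12) {
      # no within-replicate variation anywhere: the test is degenerate
      warning("degenerate table: no within-replicate rank variation")
      stat <- 0; pval <- 1; param <- c(`num df` = K - 1, `denom df` = (J - 1) * (K - 1))
    } else {
      # perfectly consistent rankings: permutation bound, as in quade.test
      stat <- NaN; pval <- gamma(K + 1)^(1 - J)
      param <- c(`num df` = NA, `denom df` = NA)
    }
  } else {
    stat <- (J - 1) * B / (A - B)
    param <- c(`num df` = K - 1, `denom df` = (J - 1) * (K - 1))
    pval <- pf(stat, param[1L], param[2L], lower.tail = FALSE)
  }
  structure(list(statistic = c(`Quade F` = stat), parameter = param,
                 p.value = unname(pval),
                 method = "Quade test (blocks weighted by ranked totals)",
                 data.name = "count table"),
            class = "htest")
}

#' One-way ANOVA on arcsine-square-root transformed proportions
#'
#' Per-replicate proportions x_jk / n_j are variance-stabilized by
#' arcsin(sqrt(.)) and compared across the K choice categories by an F test.
#' The default is the randomized-block layout (choice + replicate), with
#' (K - 1, (J - 1)(K - 1)) degrees of freedom for the choice factor: because
#' each replicate's proportions sum to 1 they are negatively correlated
#' across choices, and the unblocked one-way layout is anticonservative
#' under the no-preference null, while the blocked layout is well
#' calibrated.  Set `blocked = FALSE` for the plain one-way layout with
#' (K - 1, K(J - 1)) df.
#'
#' @param table a [count_table()]; every replicate total must be positive.
#' @param blocked block on replicate (default `TRUE`); see above.
#' @return an object of class `htest`.
#' @export
arcsine_anova <- function(table, blocked = TRUE) {
  stopifnot(inherits(table, "count_table"))
  if (any(totals(table) == 0L)) {
    stop("replicates with zero total count have undefined proportions; ",
         "exclude them before calling arcsine_anova()")
  }
  J <- nrow(table); K <- ncol(table)
  props <- unclass(table) / totals(table)
  yv <- asin(sqrt(as.numeric(props)))
  if (diff(range(yv)) < 1e-12) {
    warning("degenerate table: transformed proportions are constant")
    return(structure(list(
      statistic = c(`F` = 0),
      parameter = c(`num df` = K - 1,
                    `denom df` = if (blocked) (J - 1) * (K - 1) else K * (J - 1)),
      p.value = 1,
      method = sprintf("%s ANOVA on arcsin-sqrt proportions",
                       if (blocked) "Blocked" else "One-way"),
      data.name = "count table"), class = "htest"))
  }
  choice <- factor(rep(seq_len(K), each = J))
  dat <- data.frame(y = yv, choice = choice,
                    rep = factor(rep(seq_len(J), K)))
  fml <- if (blocked) y ~ choice + rep else y ~ choice
  av <- anova(lm(fml, data = dat))
  stat <- av["choice", "F value"]
  param <- c(`num df` = av["choice", "Df"], `denom df` = av["Residuals", "Df"])
  pval <- av["choice", "Pr(>F)"]
  if (is.nan(stat)) {  # zero between- and within-group variance
    warning("degenerate table: transformed proportions are constant")
    stat <- 0; pval <- 1
  }
  structure(list(statistic = c(`F` = stat), parameter = param,
                 p.value = unname(pval),
                 method = sprintf("%s ANOVA on arcsin-sqrt proportions",
                                  if (blocked) "Blocked" else "One-way"),
                 data.name = "count table"),
            class = "htest")
}
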