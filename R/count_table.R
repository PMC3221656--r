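#' Replicate-by-choice count table
#'
#' Construct a validated table of choice counts: one row per replicate
#' (an individual female, an arena, a cage, ...) and one column per choice
#' category (host plant, substrate, ...).  All downstream model fitting,
#' classical testing, and simulation functions operate on this container.
#'
#' Replicates whose total count is zero are legal — their individual-level
#' posterior is just the conditional prior — but they carry no likelihood
#' information, so a warning is emitted when they are present.
#'
#' @param counts matrix (or coercible) of non-negative integer counts,
#'   J replicates by K >= 2 choices.
#' @param replicate_labels character vector of row labels; defaults to
#'   existing rownames or `rep1..repJ`.
#' @param choice_labels character vector of column labels; defaults to
#'   existing colnames or `choice1..choiceK`.
#' @param population character scalar naming the population the replicates
#'   were sampled from.
#'
#' @return An object of class `count_table`: the integer count matrix with
#'   attributes `totals` (row sums) and `population`.
#' @examples
#' ct <- count_table(rbind(c(2, 1), c(0, 3)))
#' totals(ct)
#' @export
count_table <- function(counts, replicate_labels = NULL, choice_labels = NULL,
                        population = "pop1") {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("'counts' must be a numeric matrix of non-negative integers")
  }
  if (nrow(counts) < 1L || ncol(counts) < 2L) {
    stop("count table needs at least 1 replicate (row) and 2 choices (columns)")
  }
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "invalid count at row %d, column %d: entries must be non-negative integers",
      bad[1L, 1L], bad[1L, 2L]))
  }
  storage.mode(counts) <- "integer"
  J <- nrow(counts)
  K <- ncol(counts)
  if (is.null(replicate_labels)) {
    replicate_labels <- rownames(counts)
    if (is.null(replicate_labels)) replicate_labels <- paste0("rep", seq_len(J))
  }
  if (is.null(choice_labels)) {
    choice_labels <- colnames(counts)
    if (is.null(choice_labels)) choice_labels <- paste0("choice", seq_len(K))
  }
  if (length(replicate_labels) != J) stop("replicate_labels length must equal nrow(counts)")
  if (length(choice_labels) != K) stop("choice_labels length must equal ncol(counts)")
  dimnames(counts) <- list(as.character(replicate_labels),
                           as.character(choice_labels))
  tot <- as.integer(rowSums(counts))
  if (any(tot == 0L)) {
    warning(sprintf(
      "%d replicate(s) have zero total count; they are retained (their posterior equals the conditional prior)",
      sum(tot == 0L)))
  }
  structure(counts,
            totals = tot,
            population = as.character(population)[1L],
            class = c("count_table", "matrix", "array"))
}

#' @rdname count_table
#' @param x a `count_table`.
#' @export
totals <- function(x) {
  stopifnot(inherits(x, "count_table"))
  attr(x, "totals")
}

#' @rdname count_table
#' @export
population_label <- function(x) {
  stopifnot(inherits(x, "count_table"))
  attr(x, "population")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d replicates x %d choices (population '%s')\n",
              nrow(x), ncol(x), population_label(x)))
  m <- cbind(unclass(x), total = totals(x))
  print(m, ...)
  invisible(x)
}

#' Read a count table from a delimited text file
#'
#' Expects a header row of choice labels and a first column of replicate
#' labels; the body must be non-negative integers.
#'
#' @param path file path.
#' @param sep field delimiter; `""` (default) auto-detects tab vs comma from
#'   the first line.
#' @param population population label; defaults to the file name without
#'   extension.
#' @return a [count_table()].
#' @export
read_count_table <- function(path, sep = "", population = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (identical(sep, "")) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = sep, row.names = 1L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(population)) {
    population <- sub("\\.[^.]*$", "", basename(path))
  }
  count_table(as.matrix(df), population = population)
}

#' Write a count table to a delimited text file
#'
#' Inverse of [read_count_table()]: the written file round-trips exactly.
#'
#' @param x a `count_table`.
#' @param path output file path.
#' @param sep field delimiter (default tab).
#' @export
write_count_table <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "count_table"))
  df <- as.data.frame(unclass(x))
  write.table(df, path, sep = sep, quote = FALSE, col.names = NA)
  invisible(path)
}

#' Individual-level preference matrix
#'
#' Validates a J x K matrix of multinomial preference probabilities, one
#' row per replicate.  Rows must lie strictly inside the probability
#' simplex (every entry positive, each row summing to one), which keeps
#' every log-density finite.
#'
#' @param probs numeric matrix, rows on the open simplex.
#' @return the matrix with class `individual_prefs`.
#' @export
individual_prefs <- function(probs) {
  probs <- as.matrix(probs)
  if (any(!is.finite(probs)) || any(probs <= 0) || any(probs >= 1)) {
    stop("preference probabilities must lie strictly inside (0, 1)")
  }
  if (any(abs(rowSums(probs) - 1) > 1e-10)) {
    stop("each row of 'probs' must sum to 1 (tolerance 1e-10)")
  }
  structure(probs, class = c("individual_prefs", "matrix", "array"))
}

#' Population-level Dirichlet parameters
#'
#' The population distribution of individual preferences is
#' Dirichlet(w * q): `q` is the mean preference vector (a point on the
#' simplex) and `w > 0` is the concentration, inversely proportional to the
#' among-individual variance.
#'
#' @param q simplex vector of mean preferences (length K, entries > 0,
#'   summing to 1 within 1e-10).
#' @param w positive concentration scalar.
#' @return list with elements `q`, `w`, and `alpha = w * q`, class
#'   `pop_params`.
#' @export
pop_params <- function(q, w) {
  q <- as.numeric(q)
  if (any(!is.finite(q)) || any(q <= 0)) stop("all elements of 'q' must be finite and > 0")
  if (abs(sum(q) - 1) > 1e-10) stop("'q' must sum to 1 (tolerance 1e-10)")
  if (!is.finite(w) || length(w) != 1L || w <= 0) stop("'w' must be a positive scalar")
  structure(list(q = q, w = w, alpha = w * q), class = "pop_params")
}

#' Prior configuration for the population-level parameters
#'
#' The mean preference vector `q` gets a Dirichlet prior (flat,
#' all-ones, by default) and the concentration `w` a proper uniform prior
#' on (0, `w_upper`).
#'
#' @param K number of choice categories (used to build the default flat
#'   Dirichlet prior).
#' @param q_prior_alpha Dirichlet hyperparameters for `q`; default
#'   `rep(1, K)`.
#' @param w_upper upper bound `u` of the uniform prior on `w`; default 1000,
#'   far above any concentration identifiable from tens of replicates, so the
#'   prior is effectively uninformative while remaining proper.
#' @return list of class `prior_config`.
#' @export
prior_config <- function(K, q_prior_alpha = rep(1, K), w_upper = 1000) {
  q_prior_alpha <- as.numeric(q_prior_alpha)
  if (any(!is.finite(q_prior_alpha)) || any(q_prior_alpha <= 0)) {
    stop("'q_prior_alpha' entries must be positive")
  }
  if (!missing(K) && length(q_prior_alpha) != K) {
    stop("length of 'q_prior_alpha' must equal K")
  }
  if (!is.finite(w_upper) || w_upper <= 0) stop("'w_upper' must be positive")
  structure(list(q_prior_alpha = q_prior_alpha, w_upper = w_upper),
            class = "prior_config")
}

#' Population grouping scheme
#'
#' A partition of population labels into groups whose populations are
#' constrained to share the same population-level preference parameters
#' (q, w) in a grouped model fit.
#'
#' @param groups list of character vectors; must be pairwise disjoint.
#' @return list of class `grouping_scheme`.
#' @examples
#' grouping_scheme(list(c("CP", "MR"), c("GV", "VE")))
#' @export
grouping_scheme <- function(groups) {
  if (!is.list(groups) || length(groups) == 0L) stop("'groups' must be a non-empty list")
  groups <- lapply(groups, as.character)
  if (any(lengths(groups) == 0L)) stop("groups must be non-empty")
  all_pops <- unlist(groups)
  if (anyDuplicated(all_pops)) stop("groups must be pairwise disjoint")
  structure(list(groups = groups, populations = all_pops),
            class = "grouping_scheme")
}

#' @export
format.grouping_scheme <- function(x, ...) {
  paste(vapply(x$groups, function(g) paste0("(", paste(g, collapse = ","), ")"),
               character(1)), collapse = "")
}

#' @export
print.grouping_scheme <- function(x, ...) {
  cat("grouping_scheme:", format(x), "\n")
  invisible(x)
}
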