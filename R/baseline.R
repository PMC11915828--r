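#' Random-selection coverage baseline
#'
#' Monte-Carlo baseline for the greedy minimizer: each iteration draws a
#' uniform random permutation of all extracts (nested random libraries of
#' every size at once) and accumulates scaffold coverage along it. Reports
#' per-k summaries of the coverage fraction and, for each requested
#' threshold, the per-iteration first-passage library size (the number of
#' random extracts needed to reach that diversity fraction) with its mean.
#'
#' @param membership a \code{membership_map}.
#' @param n_iter number of random permutations.
#' @param seed integer master seed; the whole summary is reproducible from it.
#' @param thresholds coverage fractions for which first-passage sizes are
#'   recorded.
#' @param keep_iterations also return the full iteration x k matrix of
#'   coverage fractions (for calibration checks).
#' @return object of class \code{random_baseline}: list with \code{n_iter},
#'   \code{seed}, \code{coverage} (data.frame \code{k}, \code{mean},
#'   \code{median}, \code{q25}, \code{q75}), \code{extracts_to_fraction}
#'   (iteration x threshold integer matrix) and \code{mean_extracts_to_fraction}
#'   (named numeric).
#' @export
random_coverage <- function(membership, n_iter = 1000, seed = 1,
                            thresholds = c(0.8, 0.95, 1.0),
                            keep_iterations = FALSE) {
  stopifnot(inherits(membership, "membership_map"))
  if (n_iter < 1) sp_arg_error("n_iter must be >= 1")
  n <- length(membership$extracts)
  universe <- membership$universe
  n_univ <- length(universe)
  # invert the map: for each scaffold, which extracts carry it
  scaff <- unlist(membership$scaffolds_of[membership$extracts], use.names = FALSE)
  extr <- rep(seq_len(n), lengths(membership$scaffolds_of[membership$extracts]))
  carriers <- split(extr, factor(scaff, levels = universe))
  targets <- ceiling(thresholds * n_univ - 1e-9)  # scaffold counts to reach

  set.seed(seed)
  cov_mat <- matrix(0L, nrow = n_iter, ncol = n)
  first_pass <- matrix(NA_integer_, nrow = n_iter, ncol = length(thresholds))
  for (it in seq_len(n_iter)) {
    perm <- sample.int(n)
    # first-appearance position of each scaffold along the permutation
    inv <- integer(n); inv[perm] <- seq_len(n)
    firstpos <- vapply(carriers, function(e) min(inv[e]), integer(1))
    counts <- cumsum(tabulate(firstpos, nbins = n))
    cov_mat[it, ] <- counts
    first_pass[it, ] <- vapply(targets, function(tg) which(counts >= tg)[1],
                               integer(1))
  }
  frac <- cov_mat / n_univ
  colnames(first_pass) <- paste0(thresholds)
  structure(c(if (keep_iterations) list(iterations = frac), list(
    n_iter = n_iter, seed = seed, thresholds = thresholds,
    coverage = data.frame(
      k = seq_len(n),
      mean = colMeans(frac),
      median = apply(frac, 2, stats::median),
      q25 = apply(frac, 2, stats::quantile, probs = 0.25, names = FALSE),
      q75 = apply(frac, 2, stats::quantile, probs = 0.75, names = FALSE)),
    extracts_to_fraction = first_pass,
    mean_extracts_to_fraction = colMeans(first_pass))),
    class = "random_baseline")
}

#' @export
print.random_baseline <- function(x, ...) {
  cat(sprintf("Random baseline: %d iterations (seed %d)\n", x$n_iter, x$seed))
  cat("Mean extracts to reach diversity fraction:\n")
  print(round(x$mean_extracts_to_fraction, 1))
  invisible(x)
}

#' Expected random coverage, closed form
#'
#' Exact expectation of the scaffold-coverage count after drawing k extracts
#' uniformly without replacement: a scaffold carried by m of the n extracts
#' is missed with probability choose(n-m, k)/choose(n, k), so
#' E[covered at k] = sum_s (1 - C(n - m_s, k) / C(n, k)). Used as the
#' analytic reference for the Monte-Carlo baseline.
#'
#' @param membership a \code{membership_map}.
#' @param k vector of library sizes (defaults to 1..n).
#' @return numeric vector of expected coverage fractions at each k.
#' @export
expected_random_coverage <- function(membership,
                                     k = seq_along(membership$extracts)) {
  n <- length(membership$extracts)
  scaffold <- unlist(membership$scaffolds_of, use.names = FALSE)
  m_s <- table(factor(scaffold, levels = membership$universe))
  vapply(k, function(kk) {
    miss <- exp(lchoose(n - as.numeric(m_s), kk) - lchoose(n, kk))
    sum(1 - miss) / length(membership$universe)
  }, numeric(1))
}

#' Hit-rate quartiles of size-matched random libraries
#'
#' Repeatedly samples \code{subset_size} extracts without replacement and
#' records the hit rate (percent of sampled extracts passing the assay
#' threshold); reports the 25th and 75th percentiles across iterations,
#' the comparison the rational library's hit rate is judged against.
#'
#' @param activity an \code{activity_table} with hit calls.
#' @param extracts extract IDs forming the sampling population.
#' @param subset_size random library size (e.g. matched to the rational
#'   library).
#' @param n_iter number of random libraries.
#' @param seed integer seed.
#' @return object of class \code{hit_rate_quartiles}: list with
#'   \code{subset_size}, \code{n_iter}, \code{lower_quartile},
#'   \code{upper_quartile} (percentages), and the full \code{hit_rates}
#'   vector.
#' @export
random_hit_rate_quartiles <- function(activity, extracts, subset_size,
                                      n_iter = 1000, seed = 1) {
  if (subset_size > length(extracts))
    sp_arg_error("subset_size exceeds the number of available extracts")
  hit <- activity$hit[match(extracts, activity$extract_id)]
  if (anyNA(hit))
    sp_stop(sprintf("missing hit calls for extract(s): %s",
                    paste(utils::head(extracts[is.na(hit)], 5), collapse = ", ")))
  set.seed(seed)
  rates <- vapply(seq_len(n_iter), function(i) {
    100 * mean(hit[sample.int(length(hit), subset_size)])
  }, numeric(1))
  q <- stats::quantile(rates, c(0.25, 0.75), names = FALSE)  # type-7
  structure(list(subset_size = subset_size, n_iter = n_iter,
                 lower_quartile = q[1], upper_quartile = q[2],
                 hit_rates = rates),
            class = "hit_rate_quartiles")
}

#' @export
print.hit_rate_quartiles <- function(x, ...) {
  cat(sprintf(
    "Random libraries of %d extracts (%d iterations): hit-rate quartiles %.2f-%.2f%%\n",
    x$subset_size, x$n_iter, x$lower_quartile, x$upper_quartile))
  invisible(x)
}
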