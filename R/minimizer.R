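new_selection_result <- function(df, universe_size, target_fraction) {
  structure(df,
            universe_size = universe_size,
            target_fraction = target_fraction,
            class = c("selection_result", "data.frame"))
}

#' Greedy scaffold-coverage extract selection
#'
#' Builds a rational library: the first pick is the extract containing the
#' most scaffolds; each subsequent pick is the extract contributing the most
#' scaffolds not already covered. Selection stops at the first step where the
#' covered fraction of the scaffold universe reaches \code{target_fraction}
#' (inclusive), or when no extract adds a new scaffold. Extracts contributing
#' zero new scaffolds are never selected.
#'
#' @param membership a \code{membership_map} from [build_membership()].
#' @param target_fraction fraction of maximal scaffold diversity to reach,
#'   in (0, 1].
#' @param tie_break among extracts with equal marginal gain:
#'   \code{"lex"} picks the lexicographically smallest extract ID (default,
#'   deterministic across input orderings); \code{"input-order"} picks the
#'   first in input order.
#' @return a \code{selection_result}: data.frame with columns \code{rank},
#'   \code{extract_id}, \code{new_scaffolds}, \code{cumulative_scaffolds},
#'   \code{cumulative_fraction}; attributes \code{universe_size} and
#'   \code{target_fraction}.
#' @examples
#' m <- structure(list(
#'   extracts = c("A", "B", "C"),
#'   scaffolds_of = list(A = 1:3, B = 2:3, C = 4L),
#'   universe = 1:4), class = "membership_map")
#' greedy_select(m, 1.0)  # picks A then C; B is fully redundant
#' @export
greedy_select <- function(membership, target_fraction = 1.0,
                          tie_break = c("lex", "input-order")) {
  tie_break <- match.arg(tie_break)
  stopifnot(inherits(membership, "membership_map"))
  if (!is.numeric(target_fraction) || length(target_fraction) != 1 ||
      is.na(target_fraction) || target_fraction <= 0 || target_fraction > 1)
    sp_arg_error("target_fraction must be a single number in (0, 1]")

  extracts <- membership$extracts
  universe <- membership$universe
  n_univ <- length(universe)
  # scaffold IDs -> dense indices for O(1) coverage bookkeeping
  sets <- lapply(membership$scaffolds_of[extracts],
                 function(s) match(s, universe))
  covered <- logical(n_univ)
  order_ids <- character(0)
  new_covered <- integer(0)
  candidates <- seq_along(extracts)

  repeat {
    gains <- vapply(candidates, function(i) sum(!covered[sets[[i]]]), integer(1))
    best_gain <- max(gains)
    if (best_gain == 0L) break            # zero-gain stop (defensive guard)
    tied <- candidates[gains == best_gain]
    pick <- if (tie_break == "lex") tied[order(extracts[tied])[1]] else tied[1]
    covered[sets[[pick]]] <- TRUE
    order_ids <- c(order_ids, extracts[pick])
    new_covered <- c(new_covered, best_gain)
    candidates <- setdiff(candidates, pick)
    if (sum(covered) / n_univ >= target_fraction || !length(candidates)) break
  }

  cum <- cumsum(new_covered)
  new_selection_result(
    data.frame(rank = seq_along(order_ids),
               extract_id = order_ids,
               new_scaffolds = new_covered,
               cumulative_scaffolds = cum,
               cumulative_fraction = cum / n_univ),
    universe_size = n_univ,
    target_fraction = target_fraction)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "Rational library: %d extracts covering %d/%d scaffolds (%.1f%%), target %.0f%%\n",
    nrow(x), x$cumulative_scaffolds[nrow(x)], attr(x, "universe_size"),
    100 * x$cumulative_fraction[nrow(x)], 100 * attr(x, "target_fraction")))
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Greedy diversity accumulation curve
#'
#' Runs the greedy selection to completion (target 1.0) and returns the
#' cumulative scaffold-coverage fraction after each pick.
#'
#' @inheritParams greedy_select
#' @return a \code{diversity_curve}: data.frame with columns \code{k}
#'   (number of extracts selected) and \code{fraction}.
#' @export
diversity_curve <- function(membership, tie_break = c("lex", "input-order")) {
  sel <- greedy_select(membership, target_fraction = 1.0,
                       tie_break = match.arg(tie_break))
  structure(data.frame(k = sel$rank, fraction = sel$cumulative_fraction),
            class = c("diversity_curve", "data.frame"))
}

#' Library size needed to reach a diversity fraction
#'
#' @param curve a \code{diversity_curve}.
#' @param fraction coverage fraction in (0, 1].
#' @return the smallest k with \code{curve$fraction[k] >= fraction};
#'   \code{NA_integer_} (with a warning) if the curve never reaches it.
#' @export
extracts_to_fraction <- function(curve, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      is.na(fraction) || fraction <= 0 || fraction > 1)
    sp_arg_error("fraction must be a single number in (0, 1]")
  k <- which(curve$fraction >= fraction)
  if (!length(k)) {
    warning(sprintf("curve never reaches fraction %g (max %g)",
                    fraction, max(curve$fraction)), call. = FALSE)
    return(NA_integer_)
  }
  curve$k[k[1]]
}

#' Fold reduction in library size
#'
#' @param full_size number of extracts in the full library.
#' @param reduced_size number of extracts in the minimized library.
#' @param digits decimal places for presentation rounding (conventional
#'   half-up; \code{NULL} returns full precision).
#' @return \code{full_size / reduced_size}, rounded if requested.
#' @examples
#' fold_reduction(1439, 50)   # 28.8
#' fold_reduction(1439, 216)  # 6.7
#' @export
fold_reduction <- function(full_size, reduced_size, digits = 1) {
  if (!is.numeric(full_size) || !is.numeric(reduced_size) ||
      full_size <= 0 || reduced_size <= 0)
    sp_arg_error("library sizes must be positive")
  if (reduced_size > full_size)
    sp_arg_error("reduced_size must not exceed full_size")
  x <- full_size / reduced_size
  if (is.null(digits)) x else round(x + 1e-12, digits)  # half-up at .5 ties
}
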