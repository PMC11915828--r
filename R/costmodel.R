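#' Define a screening-cost scenario
#'
#' Compares two strategies over repeated screening campaigns: screening the
#' full library of N extracts in every assay, versus paying the upfront
#' LC-MS acquisition cost for all N extracts once and then screening only
#' the rational library of n extracts in every assay.
#'
#' @param full_size N, extracts in the full library.
#' @param reduced_size n, extracts in the rational library (0 < n <= N).
#' @param lcms_cost LC-MS acquisition cost per extract (currency units).
#' @param assay_cost assay cost per extract per assay ("cost per well",
#'   single concentration, one extract per well).
#' @param max_assays number of assay campaigns to tabulate.
#' @return object of class \code{cost_scenario}.
#' @export
cost_scenario <- function(full_size, reduced_size, lcms_cost, assay_cost,
                          max_assays = 10) {
  if (reduced_size <= 0 || reduced_size > full_size)
    sp_arg_error("need 0 < reduced_size <= full_size")
  if (lcms_cost < 0 || assay_cost < 0) sp_arg_error("costs must be >= 0")
  structure(list(full_size = full_size, reduced_size = reduced_size,
                 lcms_cost = lcms_cost, assay_cost = assay_cost,
                 max_assays = as.integer(max_assays)),
            class = "cost_scenario")
}

#' Cumulative screening costs per assay count
#'
#' full(k) = k * N * assay_cost;
#' rational(k) = N * lcms_cost + k * n * assay_cost, for k = 0..max_assays.
#'
#' @param s a \code{cost_scenario}.
#' @return data.frame with columns \code{assays}, \code{full_cost},
#'   \code{rational_cost}, \code{saving}.
#' @export
cumulative_costs <- function(s) {
  stopifnot(inherits(s, "cost_scenario"))
  k <- 0:s$max_assays
  full <- k * s$full_size * s$assay_cost
  rational <- s$full_size * s$lcms_cost + k * s$reduced_size * s$assay_cost
  data.frame(assays = k, full_cost = full, rational_cost = rational,
             saving = full - rational)
}

#' Break-even assay count
#'
#' The smallest number of assay campaigns after which the rational strategy
#' is strictly cheaper than screening the full library every time:
#' the ceiling of N * lcms_cost / ((N - n) * assay_cost), bumped by one when
#' the division is exact (ties count as not-yet-saving).
#'
#' @param s a \code{cost_scenario}.
#' @return integer assay count; \code{Inf} when n = N or assay_cost = 0
#'   (savings never accrue).
#' @export
break_even_assays <- function(s) {
  stopifnot(inherits(s, "cost_scenario"))
  slope <- (s$full_size - s$reduced_size) * s$assay_cost
  if (slope <= 0) return(Inf)
  upfront <- s$full_size * s$lcms_cost
  k <- ceiling(upfront / slope)
  if (k * slope <= upfront) k <- k + 1  # strict inequality required
  as.integer(max(k, 1))
}
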