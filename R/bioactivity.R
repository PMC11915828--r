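#' Correlate feature abundance with bioactivity
#'
#' For every feature, computes the correlation between its abundance across
#' extracts and the activity score, flags bioactive-candidate features, and
#' controls the FDR across the whole feature set. Spearman (rank) correlation
#' is the default because metabolite abundance-activity relationships are
#' typically monotone but not linear; the Pearson path covers binary hit
#' calls (point-biserial). A feature is called significant when its
#' FDR-adjusted P value is below \code{alpha} and its correlation exceeds
#' \code{rho_cut} (positive correlation with activity only; P values are the
#' usual two-sided ones, with the rho cut providing directionality).
#'
#' Spearman rho is the product-moment correlation of average ranks; its P
#' value uses the t-distribution approximation
#' t = rho * sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom. Features with
#' zero abundance variance (or a constant activity vector) have no defined
#' correlation: they are reported with \code{rho = NA} and excluded from the
#' FDR family.
#'
#' @param q a \code{quant_matrix} (ideally after [quant_pipeline()]).
#' @param activity an \code{activity_table}; the \code{activity} column is
#'   used for \code{method = "spearman"}, the \code{hit} column (as 0/1) for
#'   \code{method = "pearson"}.
#' @param method correlation method.
#' @param alpha FDR level for the significance call.
#' @param rho_cut minimum correlation for the significance call.
#' @return data.frame of class \code{correlation_result} with columns
#'   \code{feature_id}, \code{method}, \code{rho}, \code{p_raw},
#'   \code{p_adj}, \code{n_pairs}, \code{significant}.
#' @export
correlate_features <- function(q, activity,
                               method = c("spearman", "pearson"),
                               alpha = 0.05, rho_cut = 0.5) {
  method <- match.arg(method)
  stopifnot(inherits(q, "quant_matrix"))
  shared <- intersect(q$sample_columns, activity$extract_id)
  if (length(shared) < 3)
    sp_stop(sprintf("only %d extract(s) shared between quant table and activity; need >= 3",
                    length(shared)))
  y <- if (method == "spearman") {
    activity$activity[match(shared, activity$extract_id)]
  } else {
    as.numeric(activity$hit[match(shared, activity$extract_id)])
  }
  if (anyNA(y)) sp_stop("missing activity values for shared extracts")
  ab <- q$abundance[, shared, drop = FALSE]
  n <- length(shared)

  if (method == "spearman") {
    x_mat <- t(apply(ab, 1, rank))          # average ranks for ties
    y_use <- rank(y)
  } else {
    x_mat <- ab
    y_use <- y
  }
  const_x <- apply(x_mat, 1, function(v) max(v) == min(v))
  const_y <- max(y_use) == min(y_use)

  rho <- rep(NA_real_, nrow(ab))
  if (!const_y && any(!const_x))
    rho[!const_x] <- as.numeric(stats::cor(t(x_mat[!const_x, , drop = FALSE]),
                                           y_use))
  p_raw <- rep(NA_real_, nrow(ab))
  ok <- !is.na(rho)
  tstat <- rho[ok] * sqrt((n - 2) / pmax(1 - rho[ok]^2, .Machine$double.eps))
  p_raw[ok] <- pmin(1, 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE))

  p_adj <- rep(NA_real_, nrow(ab))
  p_adj[ok] <- benjamini_hochberg(p_raw[ok])

  structure(data.frame(
    feature_id = q$features$feature_id,
    method = method,
    rho = rho,
    p_raw = p_raw,
    p_adj = p_adj,
    n_pairs = n,
    significant = !is.na(rho) & rho > rho_cut & p_adj < alpha),
    class = c("correlation_result", "data.frame"))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted P values (monotone-enforced, capped at 1), delegating to
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p_values numeric vector of raw P values in [0, 1].
#' @return adjusted P values, same order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    sp_arg_error("p_values must all lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Hit rate of a library
#'
#' @param selection character vector of extract IDs forming the library.
#' @param activity an \code{activity_table} with hit calls for every
#'   selected extract.
#' @return percentage of selected extracts that are assay hits.
#' @export
hit_rate <- function(selection, activity) {
  if (!length(selection)) sp_arg_error("selection is empty")
  hit <- activity$hit[match(selection, activity$extract_id)]
  if (anyNA(hit))
    sp_stop(sprintf("missing hit calls for extract(s): %s",
                    paste(utils::head(selection[is.na(hit)], 5), collapse = ", ")))
  100 * sum(hit) / length(selection)
}

#' Retention of bioactive-candidate features in rational libraries
#'
#' Checks whether each feature flagged as significantly bioactivity-correlated
#' in the full library would still be observed after minimization: a feature
#' is retained in a library when its abundance is > 0 in at least one of
#' that library's extracts.
#'
#' @param correlations a \code{correlation_result} (full-library run).
#' @param q the \code{quant_matrix} the correlations were computed on.
#' @param selections named list of \code{selection_result}s (or plain
#'   character vectors of extract IDs), e.g.
#'   \code{list("80%" = sel80, "95%" = sel95, "100%" = sel100)}.
#' @return object of class \code{retention_result}: list with
#'   \code{n_significant_full}, \code{n_retained} (named integer per
#'   library), \code{retained_ids} (named list) and \code{significant_ids}.
#' @export
retention <- function(correlations, q, selections) {
  stopifnot(inherits(q, "quant_matrix"))
  sig_ids <- correlations$feature_id[which(correlations$significant)]
  rows <- match(as.character(sig_ids), rownames(q$abundance))
  if (anyNA(rows))
    sp_stop("significant feature(s) absent from the quant matrix")
  get_ids <- function(s) if (inherits(s, "selection_result")) s$extract_id else s
  retained_ids <- lapply(selections, function(s) {
    ids <- get_ids(s)
    unknown <- setdiff(ids, colnames(q$abundance))
    if (length(unknown))
      sp_stop(sprintf("selected extract(s) absent from quant matrix: %s",
                      paste(utils::head(unknown, 5), collapse = ", ")))
    if (!length(sig_ids)) return(sig_ids[0])
    present <- rowSums(q$abundance[rows, ids, drop = FALSE] > 0) > 0
    sig_ids[present]
  })
  structure(list(n_significant_full = length(sig_ids),
                 n_retained = vapply(retained_ids, length, integer(1)),
                 retained_ids = retained_ids,
                 significant_ids = sig_ids),
            class = "retention_result")
}

#' @export
print.retention_result <- function(x, ...) {
  cat(sprintf("Bioactive candidates in full library: %d\n", x$n_significant_full))
  for (nm in names(x$n_retained))
    cat(sprintf("  retained in %s library: %d\n", nm, x$n_retained[[nm]]))
  invisible(x)
}
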