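new_filter_report <- function(n_input, n_repetitive = 0L, n_blank = 0L,
                              n_presence = 0L) {
  structure(list(n_input_features = n_input,
                 n_removed_repetitive = n_repetitive,
                 n_removed_blank = n_blank,
                 n_removed_presence = n_presence,
                 n_retained = n_input - n_repetitive - n_blank - n_presence),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Feature filtering: %d in -> %d retained\n",
    "  removed as repetitive m/z (background/oversplit): %d\n",
    "  removed by blank filter: %d\n",
    "  removed by minimum-presence filter: %d\n"),
    x$n_input_features, x$n_retained, x$n_removed_repetitive,
    x$n_removed_blank, x$n_removed_presence))
  invisible(x)
}

# combine sequentially applied reports into one accounting over the pipeline
merge_reports <- function(...) {
  reps <- list(...)
  new_filter_report(reps[[1]]$n_input_features,
                    n_repetitive = sum(vapply(reps, `[[`, 0L, "n_removed_repetitive")),
                    n_blank = sum(vapply(reps, `[[`, 0L, "n_removed_blank")),
                    n_presence = sum(vapply(reps, `[[`, 0L, "n_removed_presence")))
}

subset_features <- function(q, keep) {
  q$features <- q$features[keep, , drop = FALSE]
  rownames(q$features) <- NULL
  q$abundance <- q$abundance[keep, , drop = FALSE]
  q
}

#' Remove or merge highly repetitive m/z features
#'
#' Features sharing (nearly) the same m/z at many retention times indicate
#' chromatographic background; the same m/z at closely spaced retention
#' times indicates a peak oversplit by feature detection. Features are
#' grouped by m/z proximity (single-linkage within \code{mz_tol}); within a
#' group, members whose retention times fall within \code{rt_tol} are merged
#' into one feature (abundances summed, metadata from the most abundant
#' member); groups spanning more than \code{max_occurrences} distinct
#' retention-time clusters are removed entirely as background.
#'
#' @param q a \code{quant_matrix}.
#' @param mz_tol m/z grouping tolerance in Da.
#' @param rt_tol retention-time tolerance in minutes for oversplit merging.
#' @param max_occurrences maximum number of distinct RT clusters a single
#'   m/z may present before the whole group is called background.
#' @return list with elements \code{quant} (filtered \code{quant_matrix})
#'   and \code{report} (a \code{filter_report}).
#' @export
repetitive_mz_filter <- function(q, mz_tol = 0.01, rt_tol = 0.1,
                                 max_occurrences = 8) {
  stopifnot(inherits(q, "quant_matrix"))
  if (mz_tol <= 0 || rt_tol <= 0) sp_arg_error("tolerances must be positive")
  n_in <- nrow(q$abundance)
  if (n_in == 0)
    return(list(quant = q, report = new_filter_report(0L)))

  ord <- order(q$features$mz)
  mz <- q$features$mz[ord]
  # single-linkage m/z groups: break where the gap between neighbours > tol
  grp <- cumsum(c(1L, as.integer(diff(mz) > mz_tol)))
  groups <- split(ord, grp)

  keep_rows <- list()
  drop_merged <- 0L
  drop_background <- 0L
  new_ab <- q$abundance
  for (g in groups) {
    if (length(g) == 1L) { keep_rows[[length(keep_rows) + 1L]] <- g; next }
    rt <- q$features$rt[g]
    o <- order(rt)
    cl <- cumsum(c(1L, as.integer(diff(rt[o]) > rt_tol)))  # RT clusters
    n_clusters <- max(cl)
    if (n_clusters > max_occurrences) {   # background ladder: drop whole group
      drop_background <- drop_background + length(g)
      next
    }
    for (cc in split(g[o], cl)) {         # merge each oversplit RT cluster
      if (length(cc) == 1L) { keep_rows[[length(keep_rows) + 1L]] <- cc; next }
      rep_row <- cc[which.max(rowSums(q$abundance[cc, , drop = FALSE]))]
      new_ab[rep_row, ] <- colSums(q$abundance[cc, , drop = FALSE])
      keep_rows[[length(keep_rows) + 1L]] <- rep_row
      drop_merged <- drop_merged + length(cc) - 1L
    }
  }
  keep <- sort(unlist(keep_rows))
  q$abundance <- new_ab
  q <- subset_features(q, keep)
  list(quant = q,
       report = new_filter_report(n_in,
                                  n_repetitive = drop_merged + drop_background))
}

#' Fivefold blank removal
#'
#' Removes features attributable to the solvent or culture-medium blanks: a
#' feature is discarded when its mean abundance across sample columns fails
#' to exceed \code{fold} times its mean abundance across blank columns.
#' Features absent from every blank are always retained.
#'
#' @param q a \code{quant_matrix} with at least one blank column.
#' @param fold required sample-to-blank ratio (default 5).
#' @param blank_stat aggregate over blank columns: \code{"mean"} (default) or
#'   the more conservative \code{"max"}.
#' @return list with \code{quant} and \code{report}.
#' @export
blank_filter <- function(q, fold = 5, blank_stat = c("mean", "max")) {
  stopifnot(inherits(q, "quant_matrix"))
  blank_stat <- match.arg(blank_stat)
  if (fold <= 0) sp_arg_error("fold must be positive")
  if (!length(q$blank_columns))
    sp_config_error("blank_filter requires at least one blank column")
  n_in <- nrow(q$abundance)
  blanks <- q$abundance[, q$blank_columns, drop = FALSE]
  blank_level <- if (blank_stat == "mean") rowMeans(blanks)
                 else apply(blanks, 1, max)
  sample_mean <- rowMeans(q$abundance[, q$sample_columns, drop = FALSE])
  keep <- blank_level == 0 | sample_mean >= fold * blank_level
  list(quant = subset_features(q, keep),
       report = new_filter_report(n_in, n_blank = sum(!keep)))
}

#' Total-ion-current normalization
#'
#' Divides every sample column by its own total so feature profiles are
#' comparable across extracts of different overall signal; blank columns are
#' dropped from the output (they have served their purpose in the blank
#' filter).
#'
#' @param q a \code{quant_matrix}.
#' @return a \code{quant_matrix} whose sample columns each sum to 1.
#' @export
tic_normalize <- function(q) {
  stopifnot(inherits(q, "quant_matrix"))
  ab <- q$abundance[, q$sample_columns, drop = FALSE]
  totals <- colSums(ab)
  if (any(totals <= 0))
    sp_stop(sprintf("zero total signal in extract(s): %s",
                    paste(q$sample_columns[totals <= 0], collapse = ", ")))
  q$abundance <- sweep(ab, 2, totals, "/")
  q$blank_columns <- character(0)
  q
}

#' Minimum-presence filter
#'
#' Features detected in fewer than \code{min_extracts} sample columns are
#' dropped: a correlation coefficient against activity cannot be computed
#' meaningfully from fewer points. Presence is evaluated on the raw
#' (pre-normalization) zero pattern, which TIC normalization preserves.
#'
#' @param q a \code{quant_matrix}.
#' @param min_extracts minimum number of sample columns with abundance > 0.
#' @return list with \code{quant} and \code{report}.
#' @export
presence_filter <- function(q, min_extracts = 3) {
  stopifnot(inherits(q, "quant_matrix"))
  if (min_extracts < 1) sp_arg_error("min_extracts must be >= 1")
  n_in <- nrow(q$abundance)
  present <- rowSums(q$abundance[, q$sample_columns, drop = FALSE] > 0)
  keep <- present >= min_extracts
  list(quant = subset_features(q, keep),
       report = new_filter_report(n_in, n_presence = sum(!keep)))
}

#' Full quantitative-table preprocessing pipeline
#'
#' Applies, in order: repetitive-m/z removal (skippable), fivefold blank
#' removal, the minimum-presence filter, and TIC normalization, returning
#' the cleaned matrix plus a reconciled accounting of which filter removed
#' how many features. Presence is a zero-pattern criterion, so evaluating it
#' before normalization changes nothing except that the returned columns
#' each sum to exactly 1.
#'
#' @inheritParams repetitive_mz_filter
#' @inheritParams blank_filter
#' @inheritParams presence_filter
#' @param repetitive apply the repetitive-m/z filter.
#' @return list with \code{quant} (TIC-normalized, sample columns only) and
#'   \code{report} (a \code{filter_report} totalled over the pipeline).
#' @export
quant_pipeline <- function(q, mz_tol = 0.01, rt_tol = 0.1, max_occurrences = 8,
                           fold = 5, min_extracts = 3, repetitive = TRUE) {
  rep1 <- if (repetitive) repetitive_mz_filter(q, mz_tol, rt_tol, max_occurrences)
          else list(quant = q, report = new_filter_report(nrow(q$abundance)))
  rep2 <- blank_filter(rep1$quant, fold = fold)
  rep3 <- presence_filter(rep2$quant, min_extracts = min_extracts)
  list(quant = tic_normalize(rep3$quant),
       report = merge_reports(rep1$report, rep2$report, rep3$report))
}
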