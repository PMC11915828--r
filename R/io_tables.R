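#' Read a GNPS classical molecular networking node table
#'
#' Parses the tab-separated node table exported by a classical molecular
#' networking job. Each row is one MS/MS consensus node with its connected
#' component ("scaffold family") and the list of source files (extracts) in
#' which it was detected. GNPS marks un-networked singleton nodes with
#' component index -1; by default each such node is promoted to its own fresh
#' one-molecule scaffold, since scaffold diversity is counted over all
#' detected chemistry. Set \code{drop_singletons = TRUE} for the alternative
#' reading in which only true network components count.
#'
#' @param path path to the TSV node table.
#' @param columns named list remapping column names; entries \code{node_id},
#'   \code{component}, \code{mz}, \code{rt}, \code{sources}. Defaults match a
#'   current GNPS export (\code{"cluster index"}, \code{"componentindex"},
#'   \code{"parent mass"}, \code{"RTMean"}, \code{"UniqueFileSources"}).
#' @param source_delim delimiter separating extract names in the source
#'   column (GNPS uses \code{"|"}).
#' @param drop_singletons drop component-index -1 nodes instead of assigning
#'   fresh singleton scaffold IDs.
#' @param normalize function applied to raw source names to obtain extract
#'   IDs; see [normalize_extract_ids()].
#' @return a data.frame of class \code{node_table} with columns
#'   \code{node_id}, \code{scaffold_id}, \code{precursor_mz},
#'   \code{retention_time}, and list-column \code{sources}.
#' @seealso [build_membership()]
#' @export
read_node_table <- function(path,
                            columns = list(),
                            source_delim = "|",
                            drop_singletons = FALSE,
                            normalize = normalize_extract_ids) {
  cols <- utils::modifyList(
    list(node_id = "cluster index", component = "componentindex",
         mz = "parent mass", rt = "RTMean", sources = "UniqueFileSources"),
    columns)
  if (!file.exists(path)) sp_config_error(sprintf("node table not found: %s", path))
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (key in c("node_id", "component", "sources")) {
    if (!cols[[key]] %in% names(raw))
      sp_config_error(sprintf(
        "node table is missing required column '%s' (configured for '%s')",
        cols[[key]], key))
  }
  if (nrow(raw) == 0) {
    out <- data.frame(node_id = integer(), scaffold_id = integer(),
                      precursor_mz = numeric(), retention_time = numeric())
    out$sources <- list()
    class(out) <- c("node_table", "data.frame")
    return(out)
  }

  node_id <- suppressWarnings(as.integer(raw[[cols$node_id]]))
  component <- suppressWarnings(as.integer(raw[[cols$component]]))
  bad <- which(is.na(node_id) | is.na(component))
  if (length(bad))
    sp_stop(sprintf("unparseable node ID or component index at data row(s): %s",
                    paste(utils::head(bad, 5), collapse = ", ")))
  if (anyDuplicated(node_id))
    sp_stop("duplicate node IDs in node table (corrupt export)")

  mz <- if (cols$mz %in% names(raw))
    suppressWarnings(as.numeric(raw[[cols$mz]])) else rep(NA_real_, nrow(raw))
  rt <- if (cols$rt %in% names(raw))
    suppressWarnings(as.numeric(raw[[cols$rt]])) else rep(NA_real_, nrow(raw))

  sources <- strsplit(as.character(raw[[cols$sources]]), source_delim, fixed = TRUE)
  sources <- lapply(sources, function(s) {
    s <- s[!is.na(s) & nzchar(trimws(s))]
    unique(normalize(s))
  })
  empty <- which(lengths(sources) == 0)
  if (length(empty))
    sp_stop(sprintf("node(s) with empty source list at data row(s): %s",
                    paste(utils::head(empty, 5), collapse = ", ")))

  scaffold_id <- component
  singleton <- component == -1L
  if (drop_singletons) {
    keep <- !singleton
    node_id <- node_id[keep]; scaffold_id <- scaffold_id[keep]
    mz <- mz[keep]; rt <- rt[keep]; sources <- sources[keep]
  } else if (any(singleton)) {
    # fresh one-molecule scaffolds, guaranteed disjoint from real component IDs
    base <- max(scaffold_id[!singleton], 0L)
    scaffold_id[singleton] <- base + seq_len(sum(singleton))
  }

  out <- data.frame(node_id = node_id, scaffold_id = scaffold_id,
                    precursor_mz = mz, retention_time = rt)
  out$sources <- sources
  class(out) <- c("node_table", "data.frame")
  out
}

#' Aggregate a node table into an extract-to-scaffold membership map
#'
#' The core data structure of the minimization algorithm: for each extract,
#' the set of scaffolds (network components) detected in it, plus the
#' universe of all scaffolds in the library.
#'
#' @param nodes a \code{node_table} from [read_node_table()].
#' @return an object of class \code{membership_map}: a list with
#'   \code{extracts} (IDs in first-appearance order), \code{scaffolds_of}
#'   (named list of integer scaffold-ID vectors) and \code{universe}
#'   (sorted integer vector of all scaffold IDs).
#' @export
build_membership <- function(nodes) {
  if (!nrow(nodes)) sp_arg_error("empty node list: cannot build membership map")
  scaffold <- rep(nodes$scaffold_id, lengths(nodes$sources))
  extract <- unlist(nodes$sources, use.names = FALSE)
  extracts <- unique(extract)
  scaffolds_of <- lapply(
    split(scaffold, factor(extract, levels = extracts)),
    function(s) sort(unique(s)))
  structure(list(extracts = extracts,
                 scaffolds_of = scaffolds_of,
                 universe = sort(unique(scaffold))),
            class = "membership_map")
}

#' @export
print.membership_map <- function(x, ...) {
  cat(sprintf("Membership map: %d extracts, %d scaffolds\n",
              length(x$extracts), length(x$universe)))
  sz <- lengths(x$scaffolds_of)
  cat(sprintf("  scaffolds per extract: min %d, median %s, max %d\n",
              min(sz), format(stats::median(sz)), max(sz)))
  invisible(x)
}

#' Read an MZmine-style quantitative feature table
#'
#' Reads a CSV with one row per LC-MS feature (m/z x retention-time pair) and
#' one peak-area column per extract. Blank (solvent/medium control) columns
#' are identified by a name pattern or given explicitly; they are kept
#' separate from sample columns for the fivefold blank filter.
#'
#' @param path path to the CSV.
#' @param columns named list remapping metadata column names; entries
#'   \code{feature_id}, \code{mz}, \code{rt} (defaults \code{"row ID"},
#'   \code{"row m/z"}, \code{"row retention time"}).
#' @param blank_pattern regular expression matched (case-insensitively)
#'   against raw column names to flag blank columns.
#' @param blank_columns explicit character vector of blank column names
#'   (normalized IDs); overrides \code{blank_pattern}.
#' @param normalize function mapping raw abundance-column names to extract
#'   IDs; see [normalize_extract_ids()].
#' @return an object of class \code{quant_matrix}: a list with
#'   \code{features} (data.frame \code{feature_id}, \code{mz}, \code{rt}),
#'   \code{abundance} (feature x extract numeric matrix),
#'   \code{sample_columns} and \code{blank_columns}.
#' @export
read_quant_table <- function(path,
                             columns = list(),
                             blank_pattern = "blank",
                             blank_columns = NULL,
                             normalize = normalize_extract_ids) {
  cols <- utils::modifyList(
    list(feature_id = "row ID", mz = "row m/z", rt = "row retention time"),
    columns)
  if (!file.exists(path)) sp_config_error(sprintf("quant table not found: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (key in c("feature_id", "mz", "rt")) {
    if (!cols[[key]] %in% names(raw))
      sp_config_error(sprintf(
        "quant table is missing required column '%s' (configured for '%s')",
        cols[[key]], key))
  }
  meta_cols <- unlist(cols)
  ab_cols <- setdiff(names(raw), meta_cols)
  ab_cols <- ab_cols[nzchar(trimws(ab_cols))]      # MZmine leaves a trailing comma
  if (!length(ab_cols)) sp_config_error("quant table has no abundance columns")

  ids <- normalize(ab_cols)
  ab <- as.matrix(raw[, ab_cols, drop = FALSE])
  storage.mode(ab) <- "double"
  colnames(ab) <- ids
  if (anyNA(ab)) sp_stop("quant table contains non-numeric or missing peak areas")
  if (any(ab < 0)) sp_stop("quant table contains negative peak areas")

  if (is.null(blank_columns)) {
    blank_columns <- ids[grepl(blank_pattern, ab_cols, ignore.case = TRUE)]
  } else {
    missing <- setdiff(blank_columns, ids)
    if (length(missing))
      sp_config_error(sprintf("blank column(s) not in quant table: %s",
                              paste(missing, collapse = ", ")))
  }
  sample_columns <- setdiff(ids, blank_columns)
  if (!length(sample_columns)) sp_config_error("quant table has no sample columns")

  fid <- raw[[cols$feature_id]]
  if (anyDuplicated(fid)) sp_stop("duplicate feature IDs in quant table")
  rownames(ab) <- as.character(fid)

  structure(list(
    features = data.frame(feature_id = fid,
                          mz = as.numeric(raw[[cols$mz]]),
                          rt = as.numeric(raw[[cols$rt]])),
    abundance = ab,
    sample_columns = sample_columns,
    blank_columns = blank_columns), class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("Quant matrix: %d features x %d columns (%d samples, %d blanks)\n",
              nrow(x$abundance), ncol(x$abundance),
              length(x$sample_columns), length(x$blank_columns)))
  invisible(x)
}

#' Read an activity table
#'
#' Reads per-extract bioactivity: a continuous score (e.g. percent growth
#' inhibition) and/or a binary hit call. When a score column is present and a
#' hit threshold is configured, the hit column is derived (or checked for
#' consistency if already present). Assay hit thresholds are metadata, not
#' hardcoded: e.g. >75 percent inhibition for a P. falciparum growth assay,
#' or <30 percent of vehicle control for an enzyme assay
#' (\code{direction = "below"}).
#'
#' @param path path to a CSV with columns \code{extract_id} and
#'   \code{activity} and/or \code{hit}.
#' @param hit_threshold optional numeric threshold deriving hits from scores.
#' @param direction \code{"above"}: hit iff activity > threshold;
#'   \code{"below"}: hit iff activity < threshold.
#' @param known_extracts optional character vector (e.g. a membership map's
#'   extracts); activity rows for unknown extracts trigger a warning listing
#'   them, and are kept.
#' @return data.frame of class \code{activity_table} with columns
#'   \code{extract_id}, \code{activity} (may be NA), \code{hit} (logical,
#'   may be NA).
#' @export
read_activity_table <- function(path, hit_threshold = NULL,
                                direction = c("above", "below"),
                                known_extracts = NULL) {
  direction <- match.arg(direction)
  if (!file.exists(path)) sp_config_error(sprintf("activity table not found: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"extract_id" %in% names(raw))
    sp_config_error("activity table is missing column 'extract_id'")
  if (!nrow(raw)) sp_stop("activity table has no rows")
  if (!any(c("activity", "hit") %in% names(raw)))
    sp_config_error("activity table needs an 'activity' and/or 'hit' column")

  out <- data.frame(extract_id = normalize_extract_ids(raw$extract_id),
                    activity = if ("activity" %in% names(raw))
                      as.numeric(raw$activity) else NA_real_,
                    hit = if ("hit" %in% names(raw))
                      as.logical(raw$hit) else NA)
  if (anyDuplicated(out$extract_id)) sp_stop("duplicate extract IDs in activity table")

  if (!is.null(hit_threshold)) {
    derived <- if (direction == "above") out$activity > hit_threshold
               else out$activity < hit_threshold
    mismatch <- which(!is.na(out$hit) & !is.na(derived) & out$hit != derived)
    if (length(mismatch))
      sp_stop(sprintf(
        "hit calls inconsistent with threshold %s %s for extract(s): %s",
        if (direction == "above") ">" else "<", hit_threshold,
        paste(utils::head(out$extract_id[mismatch], 5), collapse = ", ")))
    out$hit <- ifelse(is.na(out$hit), derived, out$hit)
  }
  if (!is.null(known_extracts)) {
    unknown <- setdiff(out$extract_id, known_extracts)
    if (length(unknown))
      warning(sprintf("activity table has %d extract(s) absent from membership: %s",
                      length(unknown), paste(utils::head(unknown, 5), collapse = ", ")),
              call. = FALSE)
  }
  class(out) <- c("activity_table", "data.frame")
  out
}

## ---- result writers (tab-separated, deterministic byte-for-byte) ----------

#' Write / read a selection result
#'
#' Writers emit tab-separated tables with a small commented header carrying
#' the metadata needed to reconstruct the object; numeric columns are written
#' at full precision so that \code{read(write(x))} reproduces \code{x}
#' exactly.
#'
#' @param x a \code{selection_result} from [greedy_select()].
#' @param path output file path.
#' @return \code{write_selection}: \code{path}, invisibly.
#'   \code{read_selection}: the reconstructed \code{selection_result}.
#' @export
write_selection <- function(x, path) {
  stopifnot(inherits(x, "selection_result"))
  con <- file(path, "wb")  # binary mode: fixed LF endings on every platform
  on.exit(close(con))
  writeLines(c(sprintf("# universe_size: %d", attr(x, "universe_size")),
               sprintf("# target_fraction: %s", fmt_num(attr(x, "target_fraction"))),
               paste(c("rank", "extract_id", "new_scaffolds",
                       "cumulative_scaffolds", "cumulative_fraction"),
                     collapse = "\t")), con)
  writeLines(paste(x$rank, x$extract_id, x$new_scaffolds,
                   x$cumulative_scaffolds, fmt_num(x$cumulative_fraction),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  grab <- function(key) sub(sprintf("^# %s: ", key), "", meta[grepl(key, meta)])
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          stringsAsFactors = FALSE)
  df$extract_id <- as.character(df$extract_id)
  new_selection_result(df,
                       universe_size = as.integer(grab("universe_size")),
                       target_fraction = as.numeric(grab("target_fraction")))
}

#' Write / read a diversity curve
#'
#' @param x a \code{diversity_curve} from [diversity_curve()].
#' @param path output file path.
#' @return \code{write_curve}: \code{path}, invisibly; \code{read_curve}: the
#'   reconstructed \code{diversity_curve}.
#' @export
write_curve <- function(x, path) {
  stopifnot(inherits(x, "diversity_curve"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("k\tfraction",
               paste(x$k, fmt_num(x$fraction), sep = "\t")), con)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(df, class = c("diversity_curve", "data.frame"))
}

#' Write / read a feature-bioactivity correlation table
#'
#' @param x data.frame of class \code{correlation_result} from
#'   [correlate_features()].
#' @param path output file path.
#' @return \code{write_correlations}: \code{path}, invisibly;
#'   \code{read_correlations}: the reconstructed table.
#' @export
write_correlations <- function(x, path) {
  stopifnot(inherits(x, "correlation_result"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(paste(names(x), collapse = "\t"),
               paste(x$feature_id, x$method, fmt_num(x$rho), fmt_num(x$p_raw),
                     fmt_num(x$p_adj), x$n_pairs, x$significant, sep = "\t")),
             con)
  invisible(path)
}

#' @rdname write_correlations
#' @export
read_correlations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$method <- as.character(df$method)
  structure(df, class = c("correlation_result", "data.frame"))
}
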