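#' Normalize extract identifiers
#'
#' Strips directory paths, mzML/mzXML file extensions and MZmine's
#' " Peak area" column suffix from extract names, so that node-table source
#' lists, quant-table column names and activity-table IDs refer to the same
#' extracts. The pattern is configurable because GNPS and MZmine exports vary
#' by release.
#'
#' @param x character vector of raw extract names.
#' @param pattern regular expression removed from each name (after stripping
#'   any leading directory path).
#' @return character vector of normalized extract IDs.
#' @examples
#' normalize_extract_ids(c("dir/EX001.mzML", "EX002.mzML Peak area"))
#' @export
normalize_extract_ids <- function(x,
                                  pattern = "(\\.mz[Xx]?[Mm][Ll])?( Peak area)?$") {
  sub(pattern, "", basename(trimws(x)))
}

# internal: stop with a classed condition so the CLI can map errors to exit codes
sp_stop <- function(msg, class = "sp_data_error", call. = FALSE) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

sp_config_error <- function(msg) sp_stop(msg, class = "sp_config_error")
sp_arg_error <- function(msg) sp_stop(msg, class = "sp_arg_error")

# internal: format a double so it round-trips through read/write exactly
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    sprintf("%.17g", v)
  }, character(1))
  out
}
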