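#' Run the full synthetic workflow end to end
#'
#' Generates a synthetic library, writes its tables, then runs every stage of
#' the pipeline through the same file readers a real analysis would use:
#' greedy minimization at the requested diversity targets, the random
#' baseline (coverage and size-matched hit-rate quartiles), quantitative
#' table preprocessing, feature-bioactivity correlation, retention of
#' significant features in each rational library, and the screening-cost
#' break-even model. Writes all result tables plus \code{summary.json} and a
#' \code{provenance.json} (parameters, seed, package version, input digests)
#' into \code{dir}; the outputs are byte-reproducible given the same seed.
#'
#' @param seed integer seed driving the generator and the Monte-Carlo
#'   baselines.
#' @param dir output directory (created if needed).
#' @param config optional \code{synth_config}; default
#'   \code{synth_config(seed = seed)}.
#' @param targets diversity fractions for the rational libraries.
#' @param n_iter iterations for the random baselines.
#' @param lcms_cost,assay_costs cost parameters for the break-even model.
#' @return (invisibly) the summary list.
#' @export
run_demo <- function(seed = 1, dir = tempfile("scaffoldpick_demo"),
                     config = NULL, targets = c(0.8, 0.95, 1.0),
                     n_iter = 200, lcms_cost = 1.81,
                     assay_costs = c(1.50, 0.50)) {
  if (is.null(config)) config <- synth_config(seed = seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gen <- synth_generate(config, dir = file.path(dir, "input"))

  nodes <- read_node_table(gen$paths$node)
  mem <- build_membership(nodes)
  activity <- read_activity_table(gen$paths$activity,
                                  known_extracts = mem$extracts)

  labels <- sprintf("%g%%", 100 * targets)
  sels <- lapply(targets, function(t) greedy_select(mem, t))
  names(sels) <- labels
  for (i in seq_along(sels))
    write_selection(sels[[i]], file.path(dir, sprintf("selection_%g.tsv",
                                                      100 * targets[i])))
  curve <- diversity_curve(mem)
  write_curve(curve, file.path(dir, "greedy_curve.tsv"))

  base <- random_coverage(mem, n_iter = n_iter, seed = seed,
                          thresholds = targets)
  rand_quart <- random_hit_rate_quartiles(
    activity, mem$extracts, subset_size = nrow(sels[[1]]),
    n_iter = n_iter, seed = seed)

  quant <- read_quant_table(gen$paths$quant)
  qp <- quant_pipeline(quant)
  corr <- correlate_features(qp$quant, activity, method = "spearman")
  write_correlations(corr, file.path(dir, "correlations.tsv"))
  ret <- retention(corr, qp$quant, sels)

  scenarios <- lapply(assay_costs, function(ca)
    cost_scenario(length(mem$extracts), nrow(sels[[1]]),
                  lcms_cost = lcms_cost, assay_cost = ca))
  break_even <- vapply(scenarios, break_even_assays, numeric(1))

  summary <- list(
    seed = seed,
    library = list(n_extracts = length(mem$extracts),
                   n_scaffolds = length(mem$universe)),
    rational_sizes = as.list(stats::setNames(vapply(sels, nrow, integer(1)),
                                             labels)),
    fold_reduction = as.list(stats::setNames(
      vapply(sels, function(s) fold_reduction(length(mem$extracts), nrow(s)),
             numeric(1)), labels)),
    random_mean_extracts_to_fraction = as.list(base$mean_extracts_to_fraction),
    hit_rate = c(list(full = hit_rate(mem$extracts, activity)),
                 lapply(sels, function(s) hit_rate(s$extract_id, activity))),
    random_hit_rate_quartiles = list(lower = rand_quart$lower_quartile,
                                     upper = rand_quart$upper_quartile),
    filter_report = unclass(qp$report),
    n_significant_features = ret$n_significant_full,
    retention = as.list(ret$n_retained),
    break_even_assays = as.list(stats::setNames(
      break_even, sprintf("assay_cost_%.2f", assay_costs))))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(package = "scaffoldpick",
         version = as.character(utils::packageVersion("scaffoldpick")),
         seed = seed,
         parameters = unclass(config),
         input_md5 = as.list(tools::md5sum(unlist(gen$paths)))),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}
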