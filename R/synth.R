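#' Configure the synthetic-data generator
#'
#' Describes a synthetic fungal-extract screening library with known ground
#' truth: an extract-to-scaffold membership structure with the heavy chemical
#' redundancy typical of natural-product libraries, an MZmine-style
#' quantitative feature table with blank columns, planted background m/z
#' ladders and medium-derived features, and per-extract bioactivity with
#' planted activity-correlated features.
#'
#' Structure emulated: a few "hub" extracts carry much of the library's
#' chemistry (log-normal extract weights), most scaffolds are shared by many
#' extracts (geometric or power-law prevalence), and bioactivity is elevated
#' in extracts carrying rare scaffolds, so a diversity-maximizing selection
#' enriches for hits. Alternatively, \code{n_archetypes > 0} builds an
#' explicit high-redundancy library in which most extracts duplicate one of
#' a few archetype scaffold sets.
#'
#' @param n_extracts number of extracts (columns of the quant table).
#' @param n_scaffolds number of networked scaffolds (connected components).
#' @param prevalence per-scaffold carrier-count law: \code{"geometric"}
#'   (1 + Geom(prevalence_param)) or \code{"powerlaw"}
#'   (\code{ceiling(n_extracts * U^prevalence_param)}).
#' @param prevalence_param parameter of the prevalence law.
#' @param features_per_scaffold_lambda scaffolds carry
#'   \code{1 + Poisson(lambda)} MS/MS features each.
#' @param n_singletons un-networked nodes (GNPS component index -1), one
#'   random source extract each.
#' @param n_blanks solvent/medium blank columns.
#' @param n_background_ladders background m/z ladders planted in the quant
#'   table: the same m/z recurring at \code{ladder_length} retention times
#'   in every column.
#' @param ladder_length retention-time occurrences per background ladder.
#' @param n_media_features medium-derived features: strong in blanks, weak
#'   in samples (removed by the fivefold blank filter).
#' @param n_planted_bioactive features whose abundance is a monotone
#'   function of activity (the recoverable ground truth for the correlation
#'   stack).
#' @param planted_presence expected fraction of extracts in which a planted
#'   feature is detected (presence probability increases with activity).
#' @param activity_slope slope of the planted features' log-abundance in
#'   standardized activity (log units per SD of activity).
#' @param activity_noise_sd SD of the Gaussian noise on planted features'
#'   log-abundance.
#' @param rarity_gain activity points added per SD of rare-scaffold richness
#'   (rare = carried by at most 2 extracts); links bioactivity to rare
#'   chemistry.
#' @param assay_noise_sd SD of the assay noise on the 0-100 activity scale.
#' @param hit_threshold activity above this is a hit (percent inhibition).
#' @param n_archetypes if > 0, build the high-redundancy archetype library
#'   instead of the prevalence-law one.
#' @param archetype_fraction fraction of extracts that exactly duplicate an
#'   archetype scaffold set.
#' @param seed integer seed; a fixed seed makes the emitted tables
#'   byte-identical across calls.
#' @return a \code{synth_config} list.
#' @export
synth_config <- function(n_extracts = 200,
                         n_scaffolds = 500,
                         prevalence = c("geometric", "powerlaw"),
                         prevalence_param = 0.1,
                         features_per_scaffold_lambda = 2,
                         n_singletons = 20,
                         n_blanks = 2,
                         n_background_ladders = 5,
                         ladder_length = 12,
                         n_media_features = 15,
                         n_planted_bioactive = 10,
                         planted_presence = 0.6,
                         activity_slope = 1.0,
                         activity_noise_sd = 0.5,
                         rarity_gain = 15,
                         assay_noise_sd = 15,
                         hit_threshold = 75,
                         n_archetypes = 0,
                         archetype_fraction = 0.9,
                         seed = 42) {
  prevalence <- match.arg(prevalence)
  cfg <- as.list(environment())
  counts <- c("n_extracts", "n_scaffolds", "n_blanks")
  for (nm in counts) if (cfg[[nm]] < 1 && nm != "n_blanks")
    sp_arg_error(sprintf("%s must be positive", nm))
  if (n_extracts < 2) sp_arg_error("need at least 2 extracts")
  if (n_archetypes > 0 && n_archetypes > n_extracts)
    sp_arg_error("more archetypes than extracts")
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic library with ground truth
#'
#' Emits the three input tables of the pipeline -- a GNPS-style node table,
#' an MZmine-style quantitative table, and an activity table -- together
#' with the generator's bookkeeping (true extract-to-scaffold sets, planted
#' bioactive / background / medium feature IDs, true activity) so every
#' downstream module can be checked against known truth.
#'
#' @param config a \code{synth_config}.
#' @param dir if non-NULL, the tables are written there as
#'   \code{node_table.tsv}, \code{quant_table.csv}, \code{activity.csv}.
#' @return list with \code{tables} (data.frames \code{node}, \code{quant},
#'   \code{activity} exactly as written), \code{paths} (when \code{dir}
#'   given), and \code{truth} (list: \code{scaffolds_of}, \code{universe_size},
#'   \code{planted_ids}, \code{ladder_ids}, \code{media_ids},
#'   \code{activity}, \code{hit}, \code{config}).
#' @export
synth_generate <- function(config = synth_config(), dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_extracts
  extracts <- sprintf("EX%03d", seq_len(n))

  ## -- extract -> scaffold membership -----------------------------------
  if (cfg$n_archetypes > 0) {
    arch_of_scaffold <- sample.int(cfg$n_archetypes, cfg$n_scaffolds, replace = TRUE)
    arch_sets <- split(seq_len(cfg$n_scaffolds), arch_of_scaffold)
    n_dup <- round(cfg$archetype_fraction * n)
    assign_arch <- c(seq_len(cfg$n_archetypes),                 # each archetype used
                     sample.int(cfg$n_archetypes, n_dup - cfg$n_archetypes,
                                replace = TRUE))
    carriers_of <- vector("list", cfg$n_scaffolds)
    for (e in seq_len(n_dup)) {
      s_set <- arch_sets[[as.character(assign_arch[e])]]
      for (s in s_set) carriers_of[[s]] <- c(carriers_of[[s]], e)
    }
    # the remaining "unique extras" re-sample small subsets of the universe
    for (e in setdiff(seq_len(n), seq_len(n_dup))) {
      s_set <- sample.int(cfg$n_scaffolds, max(1, rpois(1, 5)))
      for (s in s_set) carriers_of[[s]] <- c(carriers_of[[s]], e)
    }
  } else {
    hub_weight <- exp(stats::rnorm(n, 0, 1.2))
    m_s <- switch(cfg$prevalence,
      geometric = pmin(1L + stats::rgeom(cfg$n_scaffolds, cfg$prevalence_param), n),
      powerlaw = pmin(pmax(ceiling(n * stats::runif(cfg$n_scaffolds) ^
                                     (1 / cfg$prevalence_param)), 1L), n))
    carriers_of <- lapply(m_s, function(m)
      sort(sample.int(n, m, prob = hub_weight)))
  }
  # every extract must carry at least one scaffold
  carried <- sort(unique(unlist(carriers_of)))
  for (e in setdiff(seq_len(n), carried)) {
    s <- sample.int(cfg$n_scaffolds, 1)
    carriers_of[[s]] <- sort(c(carriers_of[[s]], e))
  }
  carriers_of <- lapply(carriers_of, function(x) sort(unique(x)))

  ## -- activity: elevated in extracts rich in rare scaffolds -------------
  m_s_final <- lengths(carriers_of)
  rare <- which(m_s_final <= 2)
  rarity <- if (length(rare)) tabulate(unlist(carriers_of[rare]), nbins = n)
            else rep(0L, n)
  z_rar <- if (stats::sd(rarity) > 0) as.numeric(scale(rarity)) else rep(0, n)
  activity <- 45 + cfg$rarity_gain * z_rar + stats::rnorm(n, 0, cfg$assay_noise_sd)
  activity <- round(pmin(100, pmax(0, activity)), 2)
  hit <- activity > cfg$hit_threshold

  ## -- node table (networked features + singleton nodes + planted) -------
  n_feat_per_scaffold <- 1L + stats::rpois(cfg$n_scaffolds,
                                           cfg$features_per_scaffold_lambda)
  scaffold_of_feature <- rep(seq_len(cfg$n_scaffolds), n_feat_per_scaffold)
  n_net <- length(scaffold_of_feature)
  singleton_src <- sample.int(n, cfg$n_singletons, replace = TRUE)

  z_act <- as.numeric(scale(activity))
  planted_carriers <- lapply(seq_len(cfg$n_planted_bioactive), function(j) {
    p <- stats::plogis(stats::qlogis(cfg$planted_presence) + 1.5 * z_act)
    idx <- which(stats::runif(n) < p)
    if (length(idx) < 3) idx <- utils::head(order(activity, decreasing = TRUE), 3)
    sort(idx)
  })

  comp <- c(scaffold_of_feature,
            rep(-1L, cfg$n_singletons),
            rep(-1L, cfg$n_planted_bioactive))
  src_list <- c(lapply(scaffold_of_feature, function(s) carriers_of[[s]]),
                as.list(singleton_src),
                planted_carriers)
  n_nodes <- length(comp)
  node_mz <- round(stats::runif(n_nodes, 150, 1500), 4)
  node_rt <- round(stats::runif(n_nodes, 0.5, 12), 2)
  node_df <- data.frame(
    check.names = FALSE,
    `cluster index` = seq_len(n_nodes),
    componentindex = comp,
    `parent mass` = node_mz,
    RTMean = node_rt,
    UniqueFileSources = vapply(src_list, function(e)
      paste0(extracts[e], ".mzML", collapse = "|"), character(1)))

  ## -- quant table --------------------------------------------------------
  blanks <- if (cfg$n_blanks > 0) sprintf("Blank_%d", seq_len(cfg$n_blanks))
            else character(0)
  all_cols <- c(extracts, blanks)
  n_quant <- n_nodes + cfg$n_background_ladders * cfg$ladder_length +
    cfg$n_media_features
  ab <- matrix(0, nrow = n_quant, ncol = length(all_cols),
               dimnames = list(NULL, all_cols))
  mz <- numeric(n_quant); rt <- numeric(n_quant)
  mz[seq_len(n_nodes)] <- node_mz
  rt[seq_len(n_nodes)] <- node_rt

  for (i in seq_len(n_net)) {
    e <- src_list[[i]]
    ab[i, e] <- stats::rlnorm(length(e), meanlog = 11, sdlog = 1)
  }
  for (i in seq_len(cfg$n_singletons)) {
    row <- n_net + i
    ab[row, src_list[[row]]] <- stats::rlnorm(1, meanlog = 11, sdlog = 1)
  }
  planted_ids <- n_net + cfg$n_singletons + seq_len(cfg$n_planted_bioactive)
  for (j in seq_len(cfg$n_planted_bioactive)) {
    row <- planted_ids[j]
    e <- planted_carriers[[j]]
    ab[row, e] <- exp(11 + cfg$activity_slope * z_act[e] +
                        stats::rnorm(length(e), 0, cfg$activity_noise_sd))
  }

  row0 <- n_nodes
  ladder_ids <- integer(0)
  if (cfg$n_background_ladders > 0) {
    for (l in seq_len(cfg$n_background_ladders)) {
      base_mz <- round(stats::runif(1, 150, 1500), 4)
      rts <- round(seq(0.5, by = 0.5, length.out = cfg$ladder_length), 2)
      rows <- row0 + seq_len(cfg$ladder_length)
      mz[rows] <- base_mz + round(stats::runif(cfg$ladder_length, 0, 0.002), 4)
      rt[rows] <- rts
      ab[rows, ] <- stats::rlnorm(length(rows) * length(all_cols),
                                  meanlog = 10, sdlog = 0.3)
      ladder_ids <- c(ladder_ids, rows)
      row0 <- row0 + cfg$ladder_length
    }
  }
  media_ids <- integer(0)
  if (cfg$n_media_features > 0) {
    media_ids <- row0 + seq_len(cfg$n_media_features)
    mz[media_ids] <- round(stats::runif(cfg$n_media_features, 150, 1500), 4)
    rt[media_ids] <- round(stats::runif(cfg$n_media_features, 0.5, 12), 2)
    if (cfg$n_blanks > 0) {
      blank_level <- stats::rlnorm(cfg$n_media_features, meanlog = 12, sdlog = 0.5)
      ab[media_ids, blanks] <- blank_level     # recycled across blank columns
      ab[media_ids, extracts] <- blank_level * 0.1
    } else {
      ab[media_ids, extracts] <- stats::rlnorm(cfg$n_media_features, 12, 0.5)
    }
  }

  quant_df <- data.frame(
    check.names = FALSE,
    `row ID` = seq_len(n_quant),
    `row m/z` = mz,
    `row retention time` = rt)
  ab_named <- ab
  colnames(ab_named) <- paste0(all_cols, ".mzML Peak area")
  quant_df <- cbind(quant_df, as.data.frame(ab_named, check.names = FALSE))

  activity_df <- data.frame(extract_id = extracts, activity = activity,
                            hit = hit)

  # ground truth under the default singleton rule: every -1 node is its own
  # scaffold, so planted features and singleton nodes extend the universe
  scaffolds_of <- lapply(seq_len(n), function(e) {
    s_net <- which(vapply(carriers_of, function(cc) e %in% cc, logical(1)))
    s_single <- n_net_singleton_ids(n_net, cfg)[singleton_src == e]
    s_plant <- planted_scaffold_ids(n_net, cfg)[
      vapply(planted_carriers, function(cc) e %in% cc, logical(1))]
    sort(c(s_net, s_single, s_plant))
  })
  names(scaffolds_of) <- extracts

  out <- list(
    tables = list(node = node_df, quant = quant_df, activity = activity_df),
    truth = list(
      scaffolds_of = scaffolds_of,
      universe_size = cfg$n_scaffolds + cfg$n_singletons + cfg$n_planted_bioactive,
      planted_ids = planted_ids,
      ladder_ids = ladder_ids,
      media_ids = media_ids,
      activity = stats::setNames(activity, extracts),
      hit = stats::setNames(hit, extracts),
      config = cfg))

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(node = file.path(dir, "node_table.tsv"),
                  quant = file.path(dir, "quant_table.csv"),
                  activity = file.path(dir, "activity.csv"))
    utils::write.table(node_df, paths$node, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.csv(quant_df, paths$quant, row.names = FALSE)
    utils::write.csv(activity_df, paths$activity, row.names = FALSE)
    out$paths <- paths
  }
  out
}

# scaffold IDs that read_node_table's singleton rule will assign: fresh IDs
# after max networked component ID, in row order of the -1 nodes
n_net_singleton_ids <- function(n_net, cfg) {
  cfg$n_scaffolds + seq_len(cfg$n_singletons)
}
planted_scaffold_ids <- function(n_net, cfg) {
  cfg$n_scaffolds + cfg$n_singletons + seq_len(cfg$n_planted_bioactive)
}
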