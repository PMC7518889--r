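default_pipeline_params <- function() {
  list(bin_width = 5000, call_bin_width = 1, spike_constant = 10000,
       threshold_quantile = 0.01, min_block_width = 1,
       adjacent_min = 10000, freestanding_min = 3000,
       k_min = 2, k_max = 15, restarts = 25, seed = 1)
}

#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent named list) with a
#' sample manifest (`id`, `target`, `fragments` BED path, replicate
#' `group`), `genome` paths for primary and spike chrom.sizes, an optional
#' `control_group` whose coverage gates domain calling, stage parameters
#' under `params`, and an `output_dir`. Validation checks paths and
#' parameter sanity before any compute.
#'
#' @param config Path to a YAML file, or a named list.
#' @return The validated configuration list with defaults filled in.
#' @export
read_pipeline_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$output_dir)) stop("config: output_dir is required")
  if (is.null(cfg$genome$primary) || is.null(cfg$genome$spike))
    stop("config: genome$primary and genome$spike chrom.sizes paths required")
  for (p in c(cfg$genome$primary, cfg$genome$spike))
    if (!file.exists(p)) stop("config: missing file: ", p)
  if (length(cfg$samples) == 0L) stop("config: no samples")
  for (s in cfg$samples) {
    if (is.null(s$id) || is.null(s$fragments) || is.null(s$group))
      stop("config: every sample needs id, fragments, group")
    if (!file.exists(s$fragments))
      stop("config: missing fragment BED: ", s$fragments)
  }
  ids <- vapply(cfg$samples, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("config: duplicate sample id")
  p <- utils::modifyList(default_pipeline_params(),
                         if (is.null(cfg$params)) list() else cfg$params)
  if (p$k_min >= p$k_max) stop("config: need k_min < k_max")
  if (p$adjacent_min <= 0 || p$freestanding_min <= 0 || p$bin_width <= 0)
    stop("config: thresholds must be positive")
  groups <- unique(vapply(cfg$samples, `[[`, "", "group"))
  if (!is.null(cfg$control_group) && !cfg$control_group %in% groups)
    stop("config: control_group not among sample groups")
  diff_groups <- setdiff(groups, cfg$control_group)
  if (length(diff_groups) < 2L)
    stop("config: need at least two non-control groups to compare")
  cfg$params <- p
  cfg
}

#' Run the full domain-comparison pipeline
#'
#' Orchestrates: fragment input and spike calibration; spike-scaled binned
#' bedGraph output; per-sample domain calling (against the control group's
#' coverage when configured, else by score quantile); replicate merging
#' per group; partition of the merged lists into disjoint segments;
#' dominant-segment length filtering; spike-scaled signal matrix over the
#' surviving differential regions; knee-selected k-means clustering; and
#' FPK + spike-constant quantification per cluster. Every stage writes a
#' deterministically named file under `output_dir`, and a JSON run report
#' records spike factors, region counts surviving each step, the selected
#' k, cluster sizes, and the quantification table.
#'
#' @param config Path to a YAML configuration or a named list
#'   (see [read_pipeline_config()]).
#' @return The run report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  p <- cfg$params
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  primary <- read_chrom_sizes(cfg$genome$primary, "primary")
  spike <- read_chrom_sizes(cfg$genome$spike, "spike")

  ids <- vapply(cfg$samples, `[[`, "", "id")
  groups <- vapply(cfg$samples, `[[`, "", "group")
  frags <- setNames(lapply(cfg$samples, function(s)
    read_fragment_bed(s$fragments, primary, spike, sample_id = s$id,
                      target = if (is.null(s$target)) NA_character_ else s$target)),
    ids)
  scales <- lapply(frags, function(f)
    spike_scale_factor(f$spike_reads, p$spike_constant))

  # spike-scaled binned bedgraphs + fine tracks for calling
  fine <- list()
  for (id in ids) {
    binned <- binned_coverage(frags[[id]], primary, p$bin_width)
    write_bedgraph(scale_track(binned, scales[[id]]),
                   file.path(cfg$output_dir, paste0(id, ".scaled.bedgraph")))
    fine[[id]] <- binned_coverage(frags[[id]], primary, p$call_bin_width)
  }

  control_track <- NULL
  if (!is.null(cfg$control_group)) {
    ctrl_ids <- ids[groups == cfg$control_group]
    pooled <- do.call(rbind, lapply(ctrl_ids, function(id) frags[[id]]$primary))
    control_track <- binned_coverage(pooled, primary, p$call_bin_width)
  }

  diff_groups <- setdiff(unique(groups), cfg$control_group)
  calls <- list()
  for (id in ids[groups %in% diff_groups]) {
    calls[[id]] <- call_domains(fine[[id]], control = control_track,
                                threshold_quantile = p$threshold_quantile,
                                min_width = p$min_block_width)
    write_region_bed(calls[[id]],
                     file.path(cfg$output_dir, paste0(id, ".domains.bed")))
  }

  merged <- list()
  for (g in diff_groups) {
    gids <- ids[groups == g]
    m <- calls[[gids[1L]]]
    for (id in gids[-1L]) m <- merge_replicates(m, calls[[id]], label = g)
    attr(m, "label") <- g
    merged[[g]] <- m
    write_region_bed(m, file.path(cfg$output_dir, paste0(g, ".merged.bed")))
  }

  parts <- partition_regions(merged)
  regions <- filter_dominant(parts, p$adjacent_min, p$freestanding_min)
  write_region_bed(regions, file.path(cfg$output_dir, "differential_domains.bed"))

  # one representative fragment set per group for the clustering matrix:
  # replicates are pooled (their merged peak list already combined them)
  pooled_frags <- setNames(lapply(diff_groups, function(g) {
    gids <- ids[groups == g]
    fragment_set(g, g,
                 primary = do.call(rbind, lapply(gids, function(id)
                   frags[[id]]$primary)),
                 spike = do.call(rbind, lapply(gids, function(id)
                   frags[[id]]$spike)))
  }), diff_groups)
  pooled_scales <- lapply(pooled_frags, function(f)
    spike_scale_factor(f$spike_reads, p$spike_constant))

  mat_scaled <- signal_matrix(regions, pooled_frags, scales = pooled_scales)
  knee <- select_k_knee(mat_scaled, k_min = p$k_min, k_max = p$k_max,
                        seed = p$seed, restarts = p$restarts)
  assignment <- knee$selected
  write_matrix_tsv(mat_scaled, regions, assignment,
                   file.path(cfg$output_dir, "signal_matrix.tsv"))

  mat_raw <- signal_matrix(regions, pooled_frags, scales = NULL)
  constants <- lapply(pooled_scales, `[[`, "factor")
  mat_fpk <- fpk_scale(mat_raw, constants)
  stats_tab <- cluster_region_stats(mat_fpk, assignment)

  report <- list(
    samples = lapply(seq_along(ids), function(i) list(
      id = ids[i], group = groups[i],
      primary_fragments = nrow(frags[[ids[i]]]$primary),
      spike_reads = frags[[ids[i]]]$spike_reads,
      spike_factor = scales[[ids[i]]]$factor)),
    called_domains = lapply(calls, nrow),
    merged_domains = lapply(merged, nrow),
    partitioned_segments = nrow(parts),
    differential_regions = nrow(regions),
    selected_k = knee$k,
    withinss = as.list(knee$withinss),
    cluster_sizes = as.list(table(assignment$cluster)),
    quantification = stats_tab,
    params = p)
  jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}

write_matrix_tsv <- function(mat, regions, assignment, path) {
  df <- data.frame(chrom = regions$chrom, start = as.integer(regions$start),
                   end = as.integer(regions$end),
                   cluster = assignment$cluster,
                   as.data.frame(unclass(mat)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
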