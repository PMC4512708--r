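#' Run the full connectome pipeline from a configuration
#'
#' Wires the stages end to end: build per-subject correlation networks
#' (from supplied panels or a simulation), derive the keep-list by nodal
#' elimination on the reference condition, reduce all networks, threshold
#' per subject, group-average per condition, compute null-normalized
#' metrics at the analysis density, estimate the consensus community
#' structure, classify hubs, compare partitions across conditions, and run
#' the paired condition contrast. Every stochastic stage derives its seed
#' from the configuration seed, so reruns with the same configuration are
#' identical.
#'
#' @param config configuration as a named list or the path of a YAML file.
#'   Recognized fields (defaults in parentheses): `seed` (1), `simulate`
#'   (list passed to [simulation_spec()]; omit to supply `panels`),
#'   `panels` (list of [roi_panel()]s), `reference_condition` (the last
#'   condition), `target_density` (0.5), `min_degree_frac` (0.05),
#'   `subject_density` (0.80), `analysis_density` (0.6), `min_presence`
#'   (1.0), `nulls` (100), `iterations` (100), `n_perm` (5000),
#'   `hub_metric` ("strength").
#' @param out_dir optional directory; when given, matrices, partitions,
#'   hub tables and the summary JSON are written there.
#' @return list of class `pipeline_result` with per-condition group
#'   graphs, metric reports, consensus partitions, hub tables, pairwise
#'   partition similarities, the condition contrast, and the keep-list.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(seed = 1L, simulate = NULL, panels = NULL,
         reference_condition = NULL, target_density = 0.5,
         min_degree_frac = 0.05, subject_density = 0.80,
         analysis_density = 0.6, min_presence = 1.0, nulls = 100,
         iterations = 100, n_perm = 5000, hub_metric = "strength"),
    config)
  seed <- as.integer(cfg$seed)

  panels <- cfg$panels
  if (is.null(panels)) {
    if (is.null(cfg$simulate))
      stop("stage build: config needs either `panels` or `simulate`",
           call. = FALSE)
    spec <- do.call(simulation_spec, cfg$simulate)
    panels <- simulate_panel(spec, seed = seed)
  }
  conds <- unique(vapply(panels, function(p) p$condition, character(1)))
  ref_cond <- cfg$reference_condition %||% conds[length(conds)]
  if (!ref_cond %in% conds)
    stop("stage reduce: reference condition '", ref_cond, "' not found",
         call. = FALSE)

  # build: per-subject correlation networks per condition
  nets <- lapply(conds, function(cond)
    lapply(panels_of(panels, cond), correlation_graph))
  names(nets) <- conds

  # reduce: keep-list from the reference condition, applied to all
  keep <- tryCatch(
    eliminate_nodes(nets[[ref_cond]], cfg$target_density,
                    cfg$min_degree_frac),
    error = function(e) stop("stage reduce: ", conditionMessage(e),
                             call. = FALSE))
  reduced <- lapply(nets, function(gs) lapply(gs, subset_nodes, keep = keep))

  # threshold + average per condition
  group <- lapply(conds, function(cond) {
    thr <- lapply(reduced[[cond]], function(g) {
      if (graph_density(g) < cfg$subject_density)
        stop("stage threshold (", cond, "): subject density ",
             sprintf("%.3f", graph_density(g)), " below target ",
             cfg$subject_density, call. = FALSE)
      threshold_to_density(g, cfg$subject_density)
    })
    ga <- group_average(thr, min_presence = cfg$min_presence)
    if (graph_density(ga) < cfg$analysis_density)
      stop("stage average (", cond, "): group density ",
           sprintf("%.3f", graph_density(ga)), " below analysis density ",
           cfg$analysis_density, call. = FALSE)
    list(subject_graphs = thr,
         graph = threshold_to_density(ga, cfg$analysis_density))
  })
  names(group) <- conds

  # metrics, communities, hubs per condition
  reports <- list(); partitions <- list(); hubs <- list()
  for (k in seq_along(conds)) {
    cond <- conds[k]
    g <- group[[cond]]$graph
    reports[[cond]] <- metric_report(g, nulls = cfg$nulls,
                                     seed = seed + 100L + k)
    partitions[[cond]] <- consensus_partition(g, iterations = cfg$iterations,
                                              seed = seed + 200L + k)
    hubs[[cond]] <- hub_table(g, metric = cfg$hub_metric,
                              partition = partitions[[cond]])
  }

  # pairwise partition similarity
  sim <- NULL
  if (length(conds) > 1) {
    pairs <- utils::combn(conds, 2)
    sim <- data.frame(a = pairs[1, ], b = pairs[2, ],
                      nmi = apply(pairs, 2, function(pr)
                        partition_similarity(partitions[[pr[1]]],
                                             partitions[[pr[2]]])),
                      stringsAsFactors = FALSE)
  }

  # condition contrast: reference vs first condition, nodal strength
  contrast <- NULL
  if (length(conds) > 1) {
    base_cond <- conds[1]
    strength_of <- function(gs) t(vapply(gs, function(g) rowSums(g$weights),
                                         numeric(length(keep))))
    contrast <- paired_permutation_tmax(
      strength_of(group[[ref_cond]]$subject_graphs),
      strength_of(group[[base_cond]]$subject_graphs),
      n_perm = cfg$n_perm, seed = seed + 300L)
  }

  res <- structure(list(
    config = cfg, conditions = conds, reference_condition = ref_cond,
    keep = keep, group_graphs = lapply(group, `[[`, "graph"),
    metric_reports = reports, partitions = partitions, hub_tables = hubs,
    partition_similarity = sim, contrast = contrast, seed = seed),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (cond in res$conditions) {
    write_matrix(res$group_graphs[[cond]],
                 file.path(out_dir, paste0("group_", cond, ".tsv")))
    write_partition(res$partitions[[cond]],
                    file.path(out_dir, paste0("partition_", cond, ".tsv")),
                    node_labels = res$group_graphs[[cond]]$labels)
    utils::write.table(res$hub_tables[[cond]],
                       file.path(out_dir, paste0("hubs_", cond, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(pipeline_summary(res),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Machine-readable summary of a pipeline run
#'
#' @param res a `pipeline_result`.
#' @return nested list (suitable for JSON) with global metrics, module
#'   counts, hub-role counts, partition similarities and contrast results
#'   per condition.
#' @export
pipeline_summary <- function(res) {
  per_cond <- lapply(res$conditions, function(cond) {
    rep <- res$metric_reports[[cond]]
    ht <- res$hub_tables[[cond]]
    list(density = rep$density, C = rep$C, C_norm = rep$C_norm,
         E_glob = rep$E_glob, E_norm = rep$E_norm, sigma = rep$sigma,
         modules = res$partitions[[cond]]$m,
         Q = attr(res$partitions[[cond]], "Q"),
         n_hubs = sum(ht$is_hub),
         connector_hubs = sum(ht$role == "connector", na.rm = TRUE),
         provincial_hubs = sum(ht$role == "provincial", na.rm = TRUE),
         null_meta = rep$null_meta)
  })
  names(per_cond) <- res$conditions
  out <- list(seed = res$seed,
              n_nodes_retained = length(res$keep),
              conditions = per_cond)
  if (!is.null(res$partition_similarity))
    out$partition_similarity <- res$partition_similarity
  if (!is.null(res$contrast))
    out$contrast <- list(n_perm = res$contrast$n_perm,
                         min_p = min(res$contrast$p),
                         n_significant = sum(res$contrast$p <= 0.05))
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d conditions, %d nodes retained\n",
              length(x$conditions), length(x$keep)))
  for (cond in x$conditions)
    cat(sprintf("  %s: C = %.3f, sigma = %.3f, %d modules\n", cond,
                x$metric_reports[[cond]]$C, x$metric_reports[[cond]]$sigma,
                x$partitions[[cond]]$m))
  invisible(x)
}
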