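#' Simulation specification for synthetic ROI panels
#'
#' Defines a multi-subject, two-condition generative model for ROI time
#' series with block-modular correlation structure, a small set of
#' high-strength hub nodes with cross-module couplings, near-absent
#' negative population correlations, attenuated "weak" nodes (to exercise
#' nodal elimination), and a condition effect that raises the couplings of
#' hub-incident edges in the task condition.
#'
#' Each node's signal is a linear mix of a global latent (loading
#' `sqrt(rho_b)`), its own module's latent (loading `sqrt(rho_w - rho_b)`),
#' for hubs an extra loading `hub_cross_loading` onto every other module's
#' latent, and independent noise scaled so every signal has unit variance.
#' All latents and the noise are AR(1) processes with coefficient
#' `ar_coefficient`, giving fMRI-like temporal autocorrelation. In the task
#' condition the hub loadings (module and cross-module) are multiplied by
#' `condition_gain`; weak nodes have all their loadings multiplied by
#' `weak_attenuation`. The implied population correlation matrix is
#' available in closed form from [population_correlation()] and is
#' nonnegative by construction.
#'
#' @param n_nodes number of ROIs (default 150).
#' @param n_subjects subjects per condition (default 14).
#' @param n_time time points per series (default 150).
#' @param n_modules planted module count (default 5); ignored when
#'   `planted_partition` is given.
#' @param planted_partition optional `node_partition`; default splits nodes
#'   into `n_modules` contiguous equal blocks.
#' @param within_module_corr `rho_w`, population correlation of two
#'   ordinary nodes in one module (default 0.6).
#' @param between_module_corr `rho_b`, baseline correlation across modules
#'   (default 0.15); must be `< rho_w`.
#' @param hub_nodes indices of planted hubs (default: the first 2 nodes of
#'   each module).
#' @param hub_cross_loading loading of each hub on every other module's
#'   latent (default 0.15).
#' @param ar_coefficient AR(1) coefficient of latents and noise
#'   (default 0.3).
#' @param condition_gain multiplier (>= 1) on hub loadings in the task
#'   condition (default 1.25).
#' @param weak_nodes indices of attenuated nodes (default none).
#' @param weak_attenuation multiplier on all loadings of weak nodes
#'   (default 0.02).
#' @param conditions condition labels; the second is the "task" that
#'   receives the hub gain.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_nodes = 150, n_subjects = 14, n_time = 150,
                            n_modules = 5, planted_partition = NULL,
                            within_module_corr = 0.6,
                            between_module_corr = 0.15,
                            hub_nodes = NULL, hub_cross_loading = 0.15,
                            ar_coefficient = 0.3, condition_gain = 1.25,
                            weak_nodes = integer(0), weak_attenuation = 0.02,
                            conditions = c("rest", "task")) {
  if (n_time < 3) stop("need n_time >= 3", call. = FALSE)
  if (n_subjects < 1) stop("need at least one subject", call. = FALSE)
  if (is.null(planted_partition)) {
    # contiguous equal blocks
    planted_partition <- node_partition(
      sort(rep_len(seq_len(n_modules), n_nodes)))
  } else {
    planted_partition <- as_partition(planted_partition, n_nodes)
  }
  m <- planted_partition$m
  if (is.null(hub_nodes)) {
    hub_nodes <- unlist(lapply(seq_len(m), function(mod)
      utils::head(setdiff(which(planted_partition$assignment == mod),
                          weak_nodes), 2)))
  }
  hub_nodes <- sort(unique(as.integer(hub_nodes)))
  weak_nodes <- sort(unique(as.integer(weak_nodes)))
  if (length(hub_nodes) && (min(hub_nodes) < 1 || max(hub_nodes) > n_nodes))
    stop("hub_nodes out of range", call. = FALSE)
  if (length(weak_nodes) && (min(weak_nodes) < 1 || max(weak_nodes) > n_nodes))
    stop("weak_nodes out of range", call. = FALSE)
  if (length(intersect(hub_nodes, weak_nodes)))
    stop("a node cannot be both hub and weak", call. = FALSE)
  if (!(between_module_corr >= 0 && between_module_corr < within_module_corr
        && within_module_corr < 1))
    stop("need 0 <= rho_b < rho_w < 1", call. = FALSE)
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    stop("ar_coefficient must lie in [0, 1)", call. = FALSE)
  if (condition_gain < 1) stop("condition_gain must be >= 1", call. = FALSE)
  # variance budget of a hub in the task condition must not exceed 1
  g <- condition_gain
  hub_var <- between_module_corr +
    g^2 * (within_module_corr - between_module_corr) +
    g^2 * hub_cross_loading^2 * (m - 1)
  if (hub_var > 1)
    stop(sprintf(paste("infeasible spec: task-condition hub loadings imply",
                       "variance %.3f > 1; lower condition_gain or",
                       "hub_cross_loading"), hub_var), call. = FALSE)
  structure(list(n_nodes = n_nodes, n_subjects = n_subjects,
                 n_time = n_time, planted_partition = planted_partition,
                 within_module_corr = within_module_corr,
                 between_module_corr = between_module_corr,
                 hub_nodes = hub_nodes,
                 hub_cross_loading = hub_cross_loading,
                 ar_coefficient = ar_coefficient,
                 condition_gain = condition_gain,
                 weak_nodes = weak_nodes,
                 weak_attenuation = weak_attenuation,
                 conditions = as.character(conditions)),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(paste0("<simulation_spec> %d nodes (%d modules, %d hubs, ",
                     "%d weak), %d subjects x %d time points\n"),
              x$n_nodes, x$planted_partition$m, length(x$hub_nodes),
              length(x$weak_nodes), x$n_subjects, x$n_time))
  invisible(x)
}

# N x (1 + m) factor-loading matrix (column 1 = global latent) plus the
# per-node noise coefficient for one condition.
loading_matrix <- function(spec, condition) {
  n <- spec$n_nodes
  a <- spec$planted_partition$assignment
  m <- spec$planted_partition$m
  task <- condition == spec$conditions[length(spec$conditions)] &&
    length(spec$conditions) > 1
  gain <- if (task) spec$condition_gain else 1
  L <- matrix(0, n, m + 1)
  L[, 1] <- sqrt(spec$between_module_corr)
  L[cbind(seq_len(n), a + 1)] <-
    sqrt(spec$within_module_corr - spec$between_module_corr)
  for (h in spec$hub_nodes) {
    others <- setdiff(seq_len(m), a[h])
    L[h, others + 1] <- spec$hub_cross_loading * gain
    L[h, a[h] + 1] <- L[h, a[h] + 1] * gain
  }
  if (length(spec$weak_nodes))
    L[spec$weak_nodes, ] <- L[spec$weak_nodes, ] * spec$weak_attenuation
  noise <- sqrt(pmax(0, 1 - rowSums(L^2)))
  list(L = L, noise = noise)
}

#' Population correlation matrix implied by a simulation spec
#'
#' Closed form: with loading matrix `L` and unit-variance signals,
#' `cor = L %*% t(L)` off the diagonal. Sample correlation matrices of
#' simulated panels converge to this as the series length grows.
#'
#' @param spec a [simulation_spec()].
#' @param condition condition label (default the first, "rest").
#' @return N x N correlation matrix (unit diagonal, all entries >= 0).
#' @export
population_correlation <- function(spec, condition = spec$conditions[1]) {
  lm <- loading_matrix(spec, condition)
  r <- tcrossprod(lm$L)
  diag(r) <- 1
  r
}

ar1_series <- function(n_time, n_series, phi) {
  e <- matrix(stats::rnorm(n_time * n_series), n_time, n_series)
  if (phi == 0) return(e)
  x <- e * sqrt(1 - phi^2)
  x[1, ] <- e[1, ]
  for (t in 2:n_time) x[t, ] <- phi * x[t - 1, ] + x[t, ]
  x
}

#' Default ROI label table for simulated panels
#'
#' Generic region names with alternating hemispheres and tissue classes in
#' roughly cortical:subcortical:cerebellar proportions of a whole-brain
#' cytoarchitectonic parcellation (142:36:34).
#'
#' @param n_nodes number of ROIs.
#' @return a [roi_label_table()].
#' @export
simulated_labels <- function(n_nodes) {
  tc <- rep("cortical", n_nodes)
  n_sub <- round(n_nodes * 36 / 212)
  n_cbl <- round(n_nodes * 34 / 212)
  if (n_sub + n_cbl >= n_nodes) { n_sub <- 0; n_cbl <- 0 }
  if (n_sub > 0) tc[seq_len(n_sub) + (n_nodes - n_sub - n_cbl)] <- "subcortical"
  if (n_cbl > 0) tc[seq_len(n_cbl) + (n_nodes - n_cbl)] <- "cerebellar"
  roi_label_table(sprintf("ROI_%03d", seq_len(n_nodes)),
                  rep_len(c("L", "R"), n_nodes), tc,
                  seq_len(n_nodes))
}

#' Simulate multi-subject, multi-condition ROI time-series panels
#'
#' Draws one panel per subject per condition from the factor model of a
#' [simulation_spec()]. Latents are shared across nodes within a subject
#' and condition but drawn independently across subjects and conditions.
#' Fully reproducible from `seed`.
#'
#' @param spec a `simulation_spec`.
#' @param seed integer seed.
#' @return list of [roi_panel()]s with names `"<subject>.<condition>"`;
#'   attribute `spec` carries the generating spec.
#' @export
simulate_panel <- function(spec, seed = 1L) {
  if (!inherits(spec, "simulation_spec"))
    stop("expected a `simulation_spec`", call. = FALSE)
  set.seed(seed)
  labels <- simulated_labels(spec$n_nodes)
  m <- spec$planted_partition$m
  out <- list()
  for (s in seq_len(spec$n_subjects)) {
    sid <- sprintf("S%02d", s)
    for (cond in spec$conditions) {
      lm <- loading_matrix(spec, cond)
      z <- ar1_series(spec$n_time, m + 1, spec$ar_coefficient)
      e <- ar1_series(spec$n_time, spec$n_nodes, spec$ar_coefficient)
      x <- z %*% t(lm$L) + sweep(e, 2, lm$noise, `*`)
      out[[paste(sid, cond, sep = ".")]] <-
        roi_panel(x, subject_id = sid, condition = cond,
                  roi_labels = labels)
    }
  }
  attr(out, "spec") <- spec
  out
}

#' Extract the panels of one condition
#'
#' @param panels result of [simulate_panel()].
#' @param condition condition label.
#' @return list of `roi_panel`s, one per subject.
#' @export
panels_of <- function(panels, condition) {
  keep <- vapply(panels, function(p) p$condition == condition, logical(1))
  panels[keep]
}

#' End-to-end recovery benchmark on synthetic data
#'
#' Runs the analysis pipeline on a simulated panel set with known ground
#' truth and reports how well it is recovered: (a) the normalized mutual
#' information between the planted partition and the consensus community
#' structure of the group-averaged task network, (b) the fraction of
#' planted hubs whose normalized strength reaches the 0.7 band, and
#' (c) the outcome of the paired max-statistic permutation test contrasting
#' task and rest nodal strengths (which nodes are significant, and whether
#' any planted hub is).
#'
#' The recovered community structure is computed on the across-subject mean
#' task correlation network thresholded to `group_density`; the condition
#' contrast uses per-subject networks thresholded to a common
#' `subject_density` so that strength differences are not confounded by
#' edge-count differences.
#'
#' @param spec a [simulation_spec()].
#' @param seed integer seed driving simulation, consensus and permutations.
#' @param subject_density common per-subject threshold density for the
#'   condition contrast (default 0.60).
#' @param group_density analysis density of the mean task network (default
#'   0.60).
#' @param iterations consensus chain length (default 100).
#' @param n_perm permutations for the condition contrast (default 5000).
#' @param alpha FWE threshold for calling a node significant.
#' @return list with `nmi`, `hub_band_fraction`, `significant_nodes`,
#'   `hub_effect_detected`, `n_significant`, `consensus` and the group task
#'   graph.
#' @export
recovery_benchmark <- function(spec, seed = 1L, subject_density = 0.60,
                               group_density = 0.60, iterations = 100,
                               n_perm = 5000, alpha = 0.05) {
  panels <- simulate_panel(spec, seed = seed)
  conds <- spec$conditions
  rest_cond <- conds[1]; task_cond <- conds[length(conds)]
  raw <- lapply(conds, function(cond)
    lapply(panels_of(panels, cond), correlation_graph))
  names(raw) <- conds
  thresholded <- lapply(raw, function(gs)
    lapply(gs, threshold_to_density, target = subject_density))
  group_task <- threshold_to_density(mean_graph(raw[[task_cond]]),
                                     group_density)
  cons <- consensus_partition(group_task, iterations = iterations,
                              seed = seed + 1L)
  nmi <- partition_similarity(cons, spec$planted_partition)
  ds <- degree_strength(group_task)
  band_frac <- if (length(spec$hub_nodes)) {
    mean(ds$strength_norm[spec$hub_nodes] >= 0.7)
  } else NA_real_
  strength_of <- function(gs) t(vapply(gs, function(g) rowSums(g$weights),
                                       numeric(n_nodes(gs[[1]]))))
  pt <- paired_permutation_tmax(strength_of(thresholded[[task_cond]]),
                                strength_of(thresholded[[rest_cond]]),
                                n_perm = n_perm, seed = seed + 2L)
  sig <- which(pt$p <= alpha)
  list(nmi = nmi,
       hub_band_fraction = band_frac,
       significant_nodes = sig,
       n_significant = length(sig),
       hub_effect_detected = length(spec$hub_nodes) > 0 &&
         any(spec$hub_nodes %in% sig),
       consensus = cons,
       group_task_graph = group_task,
       permutation = pt,
       seed = seed)
}
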