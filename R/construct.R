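#' Pearson correlation network from an ROI time-series panel
#'
#' Edge weights are zero-lag Pearson correlations between ROI time series,
#' with negative correlations clamped to zero (functional connectivity
#' matrices of this kind carry a negligible number of negative entries,
#' which are removed) and a zero diagonal.
#'
#' @param panel a [roi_panel()].
#' @return a [weighted_graph()]; the number of clamped negative entries is
#'   in `attr(, "negative_count")`.
#' @export
correlation_graph <- function(panel) {
  if (!inherits(panel, "roi_panel"))
    stop("expected an `roi_panel`", call. = FALSE)
  r <- stats::cor(panel$data)
  weighted_graph(r, labels = colnames(panel$data))
}

#' Connection density (cost) of a graph
#'
#' Number of actual connections divided by the number of maximal possible
#' connections `N(N-1)/2`.
#'
#' @param graph a `weighted_graph`.
#' @return fraction in `[0, 1]`.
#' @export
graph_density <- function(graph) {
  stopifnot_graph(graph)
  n <- n_nodes(graph)
  n_edges(graph) / (n * (n - 1) / 2)
}

# Edge order used by every thresholding decision: decreasing weight, ties
# broken by lexicographic (i, j) node-pair order so results are
# deterministic.
ranked_edges <- function(graph) {
  w <- graph$weights
  ut <- which(upper.tri(w), arr.ind = TRUE)
  wt <- w[upper.tri(w)]
  keep <- wt > 0
  ut <- ut[keep, , drop = FALSE]
  wt <- wt[keep]
  o <- order(-wt, ut[, 1], ut[, 2])
  list(i = ut[o, 1], j = ut[o, 2], w = wt[o])
}

#' Threshold a graph to a target connection density
#'
#' Keeps the `floor(target * N(N-1)/2)` highest-weight edges (weakest edges
#' are removed first, i.e. edges below a data-determined fraction of the
#' maximum weight); kept weights are unchanged. Ties at the cut weight are
#' resolved by lexicographic node-pair order, so the result is deterministic
#' and densities scheduled in increasing order yield nested edge sets.
#'
#' @param graph a `weighted_graph`.
#' @param target fraction in `(0, 1]`; must not exceed the current density
#'   (thresholding never invents edges).
#' @return a `weighted_graph` with density `<= target`.
#' @export
threshold_to_density <- function(graph, target) {
  stopifnot_graph(graph)
  if (!is.numeric(target) || length(target) != 1 || target <= 0 || target > 1)
    stop("`target` must be a fraction in (0, 1]", call. = FALSE)
  cur <- graph_density(graph)
  if (target > cur + 1e-12)
    stop(sprintf("target density %.4f exceeds current density %.4f",
                 target, cur), call. = FALSE)
  n <- n_nodes(graph)
  m_keep <- floor(target * n * (n - 1) / 2)
  re <- ranked_edges(graph)
  keep <- seq_len(min(m_keep, length(re$w)))
  w <- matrix(0, n, n, dimnames = dimnames(graph$weights))
  w[cbind(re$i[keep], re$j[keep])] <- re$w[keep]
  w <- w + t(w)
  weighted_graph(w, labels = graph$labels)
}

#' Nodal elimination against a reference condition
#'
#' Implements the two-stage downsizing used to refine a whole-brain
#' parcellation against a reference network (e.g. the task of interest):
#' (1) average the per-subject reference matrices, (2) threshold the mean
#' reference network to `target_density` (removing the weakest edges, which
#' detaches the least densely interconnected nodes), and (3) drop sparsely
#' connected nodes whose remaining degree is below `min_degree_frac` of the
#' maximal possible number of nodal links `N - 1`. The returned keep-list is
#' intended to be applied identically to every other condition so that all
#' networks share nodes and edges counts.
#'
#' @param reference_graphs list of `weighted_graph`s sharing one node set
#'   (one per subject for the reference condition).
#' @param target_density density the mean reference network is thresholded
#'   to before the degree screen (default 0.5).
#' @param min_degree_frac minimum retained degree as a fraction of `N - 1`
#'   (default 0.05).
#' @return character vector of retained node labels. A warning is issued if
#'   the retained subgraph is disconnected; an empty keep-list is an error.
#' @export
eliminate_nodes <- function(reference_graphs, target_density = 0.5,
                            min_degree_frac = 0.05) {
  ref <- mean_graph(reference_graphs)
  thr <- threshold_to_density(ref, target_density)
  n <- n_nodes(thr)
  deg <- rowSums(thr$weights > 0)
  keep <- deg >= min_degree_frac * (n - 1)
  if (!any(keep)) stop("nodal elimination removed every node", call. = FALSE)
  kept <- thr$labels[keep]
  if (sum(keep) >= 2) {
    sub <- igraph::graph_from_adjacency_matrix(
      thr$weights[keep, keep] > 0, mode = "undirected")
    if (igraph::components(sub)$no > 1)
      warning("retained node set is disconnected", call. = FALSE)
  }
  kept
}

mean_graph <- function(graphs) {
  if (!length(graphs)) stop("empty graph list", call. = FALSE)
  lapply(graphs, stopifnot_graph)
  labs <- graphs[[1]]$labels
  for (g in graphs) {
    if (!identical(g$labels, labs))
      stop("graphs do not share a node set", call. = FALSE)
  }
  w <- Reduce(`+`, lapply(graphs, `[[`, "weights")) / length(graphs)
  weighted_graph(w, labels = labs)
}

#' Restrict a graph to a subset of nodes
#'
#' @param graph a `weighted_graph`.
#' @param keep character vector of node labels to retain (order preserved
#'   from the original graph).
#' @return the induced subgraph as a `weighted_graph`.
#' @export
subset_nodes <- function(graph, keep) {
  stopifnot_graph(graph)
  miss <- setdiff(keep, graph$labels)
  if (length(miss))
    stop("unknown node labels: ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  idx <- which(graph$labels %in% keep)
  weighted_graph(graph$weights[idx, idx], labels = graph$labels[idx])
}

#' Random-surrogate control for the nodal elimination strategy
#'
#' Validity check for [eliminate_nodes()]: builds synthetic surrogate
#' networks with the same number of nonzero entries as each reference graph
#' (weights shuffled onto uniformly random node pairs), repeats the
#' elimination on the surrogates, and summarizes the degree distribution of
#' the downsized surrogate network against the full one. Downsizing a
#' random network should not distort its degree-distribution shape.
#'
#' @inheritParams eliminate_nodes
#' @param seed integer seed for the surrogate construction.
#' @return list with the surrogate keep-list, degree summaries
#'   (`mean`, `sd`, `cv`) of the thresholded surrogate before and after node
#'   removal, and the ratio of the coefficients of variation.
#' @export
random_network_control <- function(reference_graphs, target_density = 0.5,
                                   min_degree_frac = 0.05, seed = 1L) {
  lapply(reference_graphs, stopifnot_graph)
  set.seed(seed)
  surrogates <- lapply(reference_graphs, function(g) {
    n <- n_nodes(g)
    wt <- g$weights[upper.tri(g$weights)]
    wt <- wt[wt > 0]
    slots <- sample(n * (n - 1) / 2, length(wt))
    w <- matrix(0, n, n)
    ut <- which(upper.tri(w))
    w[ut[slots]] <- sample(wt)
    w <- w + t(w)
    weighted_graph(w, labels = g$labels)
  })
  thr_full <- threshold_to_density(mean_graph(surrogates), target_density)
  keep <- eliminate_nodes(surrogates, target_density, min_degree_frac)
  down <- subset_nodes(thr_full, keep)
  summ <- function(g) {
    d <- rowSums(g$weights > 0)
    c(mean = mean(d), sd = stats::sd(d), cv = stats::sd(d) / mean(d))
  }
  full <- summ(thr_full); reduced <- summ(down)
  list(keep = keep, n_removed = n_nodes(thr_full) - length(keep),
       full = full, downsized = reduced,
       cv_ratio = unname(reduced["cv"] / full["cv"]),
       seed = seed)
}

#' Group-averaged network
#'
#' Consensus averaging across subjects: an edge is retained iff it is
#' present (weight > 0) in at least `min_presence` of the subjects, and the
#' retained weight is the mean of that edge's weights across all subjects.
#' With `min_presence = 1` (the default) this is an intersection rule, so
#' the group density never exceeds any input density.
#'
#' @param graphs list of `weighted_graph`s on one node set, pre-thresholded
#'   to a common density.
#' @param min_presence fraction of subjects an edge must appear in.
#' @return a `weighted_graph`.
#' @export
group_average <- function(graphs, min_presence = 1.0) {
  if (!length(graphs)) stop("empty graph list", call. = FALSE)
  mg <- mean_graph(graphs)
  pres <- Reduce(`+`, lapply(graphs, function(g) g$weights > 0)) /
    length(graphs)
  w <- mg$weights
  w[pres < min_presence] <- 0
  weighted_graph(w, labels = mg$labels)
}

#' Density schedule
#'
#' A strictly increasing set of target densities, e.g. the 60%-78% range in
#' 2% increments used for group-averaged networks.
#'
#' @param densities numeric vector of fractions in `(0, 1]`, strictly
#'   increasing.
#' @return numeric vector of class `density_schedule`.
#' @export
density_schedule <- function(densities) {
  d <- as.numeric(densities)
  if (!length(d) || any(d <= 0) || any(d > 1))
    stop("densities must lie in (0, 1]", call. = FALSE)
  if (is.unsorted(d, strictly = TRUE))
    stop("densities must be strictly increasing", call. = FALSE)
  structure(d, class = "density_schedule")
}

#' Threshold a graph at every density of a schedule
#'
#' @param graph a `weighted_graph` at least as dense as the schedule's
#'   maximum.
#' @param schedule a [density_schedule()] (or plain increasing vector).
#' @return named list of `weighted_graph`s, one per density; edge sets are
#'   nested along the schedule.
#' @export
apply_schedule <- function(graph, schedule) {
  stopifnot_graph(graph)
  sched <- density_schedule(unclass(schedule))
  cur <- graph_density(graph)
  bad <- sched[sched > cur + 1e-12]
  if (length(bad))
    stop(sprintf("scheduled density %.4f exceeds graph density %.4f",
                 bad[1], cur), call. = FALSE)
  out <- lapply(sched, function(d) threshold_to_density(graph, d))
  names(out) <- sprintf("%.4f", sched)
  out
}
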