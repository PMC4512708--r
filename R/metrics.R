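#' Nodal degree and strength
#'
#' Degree `k_i` is the number of edges incident to node `v_i`; strength
#' `s_i` is the sum of incident edge weights. Both are min-max normalized to
#' `[0, 1]`; on degenerate input (all values equal) every node maps to 1
#' with a warning.
#'
#' @param graph a `weighted_graph`.
#' @return data.frame with columns `node`, `degree`, `degree_norm`,
#'   `strength`, `strength_norm`.
#' @export
degree_strength <- function(graph) {
  stopifnot_graph(graph)
  k <- rowSums(graph$weights > 0)
  s <- rowSums(graph$weights)
  data.frame(node = graph$labels,
             degree = as.integer(k), degree_norm = normalize_minmax(k),
             strength = s, strength_norm = normalize_minmax(s),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Min-max normalization to the unit interval
#'
#' @param x numeric vector.
#' @return `(x - min) / (max - min)`; when `max == min` every entry is
#'   mapped to 1 with a warning (a uniform vector has no ordering to
#'   preserve).
#' @export
normalize_minmax <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("degenerate normalization: all values equal, mapping to 1",
            call. = FALSE)
    return(rep(1, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Weighted local clustering coefficient (geometric-mean form)
#'
#' Weights are first scaled by the network maximum, `w_hat = w / max(w)`;
#' the clustering coefficient of node `v_i` is the geometric mean of
#' triangle weights around it,
#' `c_i = sum_{j,h} (w_hat_ij w_hat_ih w_hat_jh)^(1/3) / (k_i (k_i - 1))`,
#' with `c_i = 0` for nodes of degree < 2. The global coefficient `C` is
#' the mean over nodes.
#'
#' @param graph a `weighted_graph`.
#' @return list with `local` (per-node vector in `[0, 1]`) and `global`
#'   (mean over nodes).
#' @export
clustering_coefficient <- function(graph) {
  stopifnot_graph(graph)
  w <- graph$weights
  mx <- max(w)
  ci <- numeric(n_nodes(graph))
  if (mx > 0) {
    cr <- (w / mx)^(1 / 3)
    num <- diag(cr %*% cr %*% cr)  # 2 * sum over triangles at each node
    k <- rowSums(w > 0)
    denom <- k * (k - 1)
    ok <- denom > 0
    ci[ok] <- num[ok] / denom[ok]
  }
  ci <- pmin(pmax(ci, 0), 1)
  names(ci) <- graph$labels
  list(local = ci, global = mean(ci))
}

#' Global efficiency
#'
#' Average inverse shortest path length over ordered node pairs. Edge
#' lengths are reciprocal weights (`1/w`), the standard transform for
#' correlation-weighted networks, and disconnected pairs contribute 0
#' (`1/Inf`). With weights `<= 1`, `E_glob` lies in `[0, 1]`.
#'
#' @param graph a `weighted_graph`.
#' @return scalar `E_glob`.
#' @export
global_efficiency <- function(graph) {
  stopifnot_graph(graph)
  n <- n_nodes(graph)
  ig <- igraph_from(graph)
  d <- igraph::distances(ig, weights = 1 / igraph::E(ig)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

igraph_from <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Degree-, weight- and strength-preserving null ensemble
#'
#' Generates comparable random graphs for metric normalization. Each null
#' preserves the degree sequence exactly (Maslov-Sneppen edge-pair
#' rewiring, 10 attempted swaps per edge) and the weight multiset exactly;
#' weights are re-laid onto the rewired topology by iterative rank matching
#' against the original nodal strengths, which preserves strengths
#' approximately. The mean relative per-node strength error of each null is
#' reported.
#'
#' Graphs that admit no degree-preserving rewiring (e.g. complete graphs)
#' fall back to weight shuffling on the fixed topology, with a warning.
#'
#' @param graph a `weighted_graph` with at least 2 edges.
#' @param count ensemble size (default 100).
#' @param seed integer seed.
#' @param swaps_per_edge attempted rewiring swaps per edge (default 10).
#' @param rank_period fraction of edges assigned between strength
#'   re-rankings during weight placement (default 0.05; smaller is more
#'   accurate and slower).
#' @return list of `weighted_graph`s with attributes `strength_error`
#'   (mean relative per-node strength error per null) and `seed`.
#' @export
null_ensemble <- function(graph, count = 100, seed = 1L,
                          swaps_per_edge = 10, rank_period = 0.05) {
  stopifnot_graph(graph)
  m <- n_edges(graph)
  if (m < 2) stop("need at least 2 edges to build nulls", call. = FALSE)
  n <- n_nodes(graph)
  complete <- m == n * (n - 1) / 2
  if (complete)
    warning("complete graph admits no degree-preserving rewiring; ",
            "nulls use weight shuffling only", call. = FALSE)
  ig <- igraph_from(graph)
  s_target <- rowSums(graph$weights)
  wts <- sort(graph$weights[upper.tri(graph$weights)][
    graph$weights[upper.tri(graph$weights)] > 0], decreasing = TRUE)
  set.seed(seed)
  err <- numeric(count)
  nulls <- vector("list", count)
  for (b in seq_len(count)) {
    if (complete) {
      el <- igraph::as_edgelist(ig, names = FALSE)
    } else {
      rw <- igraph::rewire(ig, igraph::keeping_degseq(
        niter = swaps_per_edge * m))
      el <- igraph::as_edgelist(rw, names = FALSE)
    }
    w <- place_weights(el, wts, s_target, n, rank_period)
    nulls[[b]] <- weighted_graph(w, labels = graph$labels)
    err[b] <- mean(abs(rowSums(w) - s_target)[s_target > 0] /
                     s_target[s_target > 0])
  }
  structure(nulls, strength_error = err, seed = seed)
}

# Lay the sorted weight multiset onto an edge list, greedily matching the
# strongest remaining weights to the edges whose endpoints have the largest
# residual target strengths; residuals are refreshed every `rank_period`
# fraction of assignments.
place_weights <- function(el, wts, s_target, n, rank_period) {
  m <- nrow(el)
  resid <- s_target
  score <- resid[el[, 1]] * resid[el[, 2]]
  unassigned <- rep(TRUE, m)
  w <- matrix(0, n, n)
  chunk <- max(1L, as.integer(round(rank_period * m)))
  pos <- 1L
  while (pos <= m) {
    take <- min(chunk, m - pos + 1L)
    idx <- which(unassigned)
    pick <- idx[order(-score[idx])[seq_len(take)]]
    # strongest residual pairs receive the strongest remaining weights
    pick <- pick[order(-score[pick])]
    ws <- wts[pos:(pos + take - 1L)]
    for (t in seq_len(take)) {
      e <- pick[t]
      w[el[e, 1], el[e, 2]] <- ws[t]
      w[el[e, 2], el[e, 1]] <- ws[t]
      resid[el[e, 1]] <- resid[el[e, 1]] - ws[t]
      resid[el[e, 2]] <- resid[el[e, 2]] - ws[t]
    }
    unassigned[pick] <- FALSE
    if (any(unassigned)) {
      iu <- which(unassigned)
      score[iu] <- resid[el[iu, 1]] * resid[el[iu, 2]]
    }
    pos <- pos + take
  }
  w
}

#' Small-world index
#'
#' `sigma = C_norm / (1 / E_norm) = C_norm * E_norm`: the ratio of the
#' null-normalized global clustering coefficient to the inverse
#' null-normalized global efficiency. Values above 1 indicate small-world
#' organization (random-graph-like integration with above-random
#' segregation).
#'
#' @param c_norm,e_norm positive null-normalized global clustering and
#'   efficiency.
#' @return scalar `sigma`.
#' @export
small_world_index <- function(c_norm, e_norm) {
  if (!is.numeric(c_norm) || !is.numeric(e_norm) ||
      any(c(c_norm, e_norm) <= 0))
    stop("normalized metrics must be positive", call. = FALSE)
  c_norm * e_norm
}

#' Per-density metric report
#'
#' Computes nodal degree/strength (raw and normalized), local and global
#' clustering, global efficiency, their null-normalized values against a
#' degree-, weight- and strength-preserving ensemble, and the small-world
#' index.
#'
#' Note that path-based metrics on correlation-derived networks capture
#' indirect as well as direct coupling and should be read with caution;
#' reports carry this caveat in their `path_metric_caveat` field.
#'
#' @param graph a `weighted_graph`.
#' @param nulls null-ensemble size (default 100).
#' @param seed integer seed for the ensemble.
#' @return object of class `metric_report`: list with `nodal` (data.frame),
#'   `clustering_local`, `C`, `E_glob`, `C_norm`, `E_norm`, `sigma`,
#'   `density`, and `null_meta`.
#' @export
metric_report <- function(graph, nulls = 100, seed = 1L) {
  stopifnot_graph(graph)
  ds <- degree_strength(graph)
  cl <- clustering_coefficient(graph)
  eg <- global_efficiency(graph)
  ens <- null_ensemble(graph, count = nulls, seed = seed)
  c_null <- vapply(ens, function(g) clustering_coefficient(g)$global, 0)
  e_null <- vapply(ens, global_efficiency, 0)
  c_norm <- cl$global / mean(c_null)
  e_norm <- eg / mean(e_null)
  structure(list(
    nodal = ds,
    clustering_local = cl$local,
    C = cl$global, E_glob = eg,
    C_norm = c_norm, E_norm = e_norm,
    sigma = small_world_index(c_norm, e_norm),
    density = graph_density(graph),
    null_meta = list(count = nulls, seed = seed,
                     mean_strength_error = mean(attr(ens, "strength_error"))),
    path_metric_caveat = paste("path-based metrics on correlation networks",
                               "reflect indirect as well as direct coupling")),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("<metric_report> density %.3f: C = %.4f ",
                     "(norm %.4f), E_glob = %.4f (norm %.4f), sigma = %.4f\n"),
              x$density, x$C, x$C_norm, x$E_glob, x$E_norm, x$sigma))
  invisible(x)
}

#' Metric reports across a density schedule
#'
#' One [metric_report()] per scheduled density; supports stability checks
#' of the global metrics across connection densities.
#'
#' @param graphs list of nested thresholded graphs from [apply_schedule()].
#' @param nulls null-ensemble size per density.
#' @param seed base seed; density `k` uses `seed + k - 1`.
#' @return list of `metric_report`s named by density.
#' @export
metrics_over_schedule <- function(graphs, nulls = 100, seed = 1L) {
  out <- vector("list", length(graphs))
  for (k in seq_along(graphs)) {
    out[[k]] <- metric_report(graphs[[k]], nulls = nulls,
                              seed = seed + k - 1L)
  }
  names(out) <- names(graphs)
  out
}
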