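#' Hub detection by the mean-plus-one-SD rule
#'
#' A node is a hub if its metric value (degree or strength) is at least one
#' standard deviation above the network average; the SD is the sample
#' (N - 1) estimator. A constant vector yields no hubs. The rule is
#' invariant under affine transforms of the metric.
#'
#' @param values per-node metric vector (length >= 2).
#' @return logical hub-flag vector.
#' @export
detect_hubs <- function(values) {
  if (length(values) < 2) stop("need at least 2 nodes", call. = FALSE)
  sdv <- stats::sd(values)
  if (sdv == 0) return(rep(FALSE, length(values)))
  values >= mean(values) + sdv
}

#' Band normalized nodal values
#'
#' Splits normalized values into the four reporting ranges used for nodal
#' influence maps: 0.9-1.0 (top 10%), 0.7-0.89 (the rest of the top 30%
#' band, lower boundary inclusive), 0.4-0.69, and <0.4.
#'
#' @param normalized_values numeric vector in `[0, 1]`.
#' @return factor with levels `"0.9-1.0"`, `"0.7-0.89"`, `"0.4-0.69"`,
#'   `"<0.4"`.
#' @export
band_nodes <- function(normalized_values) {
  x <- as.numeric(normalized_values)
  if (any(x < 0 | x > 1))
    stop("normalized values must lie in [0, 1]", call. = FALSE)
  lev <- c("0.9-1.0", "0.7-0.89", "0.4-0.69", "<0.4")
  out <- ifelse(x >= 0.9, lev[1],
                ifelse(x >= 0.7, lev[2],
                       ifelse(x >= 0.4, lev[3], lev[4])))
  factor(out, levels = lev)
}

#' Shared and distinct high-influence nodes of two networks
#'
#' Compares the top-band nodes (normalized metric at or above `threshold`,
#' default 0.7) of two networks on the same node universe.
#'
#' @param values_a,values_b named per-node normalized metric vectors (or
#'   [hub_table()] outputs) on identical node sets.
#' @param threshold normalized-value cut defining the high band.
#' @return list with character vectors `shared`, `distinct_a`,
#'   `distinct_b`.
#' @export
shared_distinct <- function(values_a, values_b, threshold = 0.7) {
  va <- extract_norm(values_a); vb <- extract_norm(values_b)
  if (!identical(names(va), names(vb)))
    stop("node universes differ between the two networks", call. = FALSE)
  in_a <- va >= threshold; in_b <- vb >= threshold
  list(shared = names(va)[in_a & in_b],
       distinct_a = names(va)[in_a & !in_b],
       distinct_b = names(va)[!in_a & in_b])
}

extract_norm <- function(x) {
  if (is.data.frame(x)) {
    v <- x$normalized
    names(v) <- x$node
    return(v)
  }
  if (is.null(names(x))) stop("values must be named by node", call. = FALSE)
  x
}

#' Participation coefficient
#'
#' `pc_i = 1 - sum_m (kappa_im / s_i)^2`, where `kappa_im` is node `i`'s
#' summed connectivity into module `m` and `s_i` its total connectivity.
#' The default is strength-weighted; `mode = "degree"` uses edge counts.
#' Isolated nodes get 0. The maximum attainable value in a network with
#' `m` modules is `1 - 1/m`.
#'
#' @param graph a `weighted_graph`.
#' @param partition a `node_partition` covering the graph.
#' @param mode `"strength"` (weights) or `"degree"` (edge counts).
#' @return per-node numeric vector in `[0, 1 - 1/m]`, named by node.
#' @export
participation_coefficient <- function(graph, partition,
                                      mode = c("strength", "degree")) {
  stopifnot_graph(graph)
  mode <- match.arg(mode)
  p <- as_partition(partition, n_nodes(graph))
  w <- if (mode == "strength") graph$weights else (graph$weights > 0) + 0
  ind <- outer(p$assignment, seq_len(p$m), `==`) + 0  # N x m indicator
  kappa <- w %*% ind
  s <- rowSums(w)
  pc <- rep(0, n_nodes(graph))
  pos <- s > 0
  pc[pos] <- 1 - rowSums((kappa[pos, , drop = FALSE] / s[pos])^2)
  pc <- pmax(pc, 0)
  names(pc) <- graph$labels
  pc
}

#' Connector / provincial hub classification
#'
#' The maximum participation coefficient in a network with `m >= 2` modules
#' is `1 - 1/m`. Hubs with `pc` within 10% of this maximum (i.e.
#' `pc >= 0.9 * (1 - 1/m)`) are connector hubs, linking modules; hubs below
#' it are provincial hubs, connecting nodes within their own community.
#' Non-hubs are classified `"none"`.
#'
#' @param hub_flags logical hub vector from [detect_hubs()].
#' @param pc per-node participation coefficients.
#' @param m module count, must be >= 2.
#' @return factor with levels `"connector"`, `"provincial"`, `"none"`.
#' @export
classify_hub_roles <- function(hub_flags, pc, m) {
  if (m < 2) stop("hub roles need m >= 2 modules", call. = FALSE)
  if (length(hub_flags) != length(pc))
    stop("`hub_flags` and `pc` lengths differ", call. = FALSE)
  thr <- 0.9 * (1 - 1 / m)
  out <- ifelse(!hub_flags, "none",
                ifelse(pc >= thr, "connector", "provincial"))
  factor(out, levels = c("connector", "provincial", "none"))
}

#' Per-node hub table
#'
#' Combines the nodal metric (degree or strength), its min-max normalized
#' value and band, the mean-plus-one-SD hub flag, and, when a partition is
#' given, the participation coefficient and connector/provincial role.
#'
#' @param graph a `weighted_graph`.
#' @param metric `"strength"` or `"degree"`.
#' @param partition optional `node_partition` for participation/roles.
#' @param pc_mode passed to [participation_coefficient()].
#' @return data.frame with columns `node`, `metric`, `value`, `normalized`,
#'   `band`, `is_hub`, and (with a partition) `pc`, `role`.
#' @export
hub_table <- function(graph, metric = c("strength", "degree"),
                      partition = NULL, pc_mode = "strength") {
  stopifnot_graph(graph)
  metric <- match.arg(metric)
  ds <- degree_strength(graph)
  value <- if (metric == "strength") ds$strength else ds$degree
  norm <- if (metric == "strength") ds$strength_norm else ds$degree_norm
  out <- data.frame(node = ds$node, metric = metric, value = value,
                    normalized = norm, band = band_nodes(norm),
                    is_hub = detect_hubs(value),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(partition)) {
    p <- as_partition(partition, n_nodes(graph))
    out$pc <- unname(participation_coefficient(graph, p, mode = pc_mode))
    out$role <- if (p$m >= 2) {
      classify_hub_roles(out$is_hub, out$pc, p$m)
    } else {
      factor(rep("none", nrow(out)),
             levels = c("connector", "provincial", "none"))
    }
  }
  out
}
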