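#' Weighted undirected graph over labeled ROI nodes
#'
#' The central container of the package: a symmetric, nonnegative weight
#' matrix with a zero diagonal over named nodes (typically atlas regions of
#' interest). Negative entries are clamped to zero at construction, mirroring
#' the removal of the sparse negative correlations in functional connectivity
#' matrices; the number of clamped entries is recorded in the
#' `negative_count` attribute.
#'
#' @param weights numeric N x N matrix; must be symmetric within `tol`
#'   (relative) and have N >= 2. The diagonal is zeroed.
#' @param labels character vector of node (region) names; defaults to the
#'   matrix dimnames or `"ROI_001"`-style names.
#' @param tol relative tolerance for the symmetry check. Asymmetries below
#'   `tol` are averaged away; anything larger is an error.
#' @return An object of class `weighted_graph`: a list with elements
#'   `weights` (matrix with dimnames) and `labels`, plus attribute
#'   `negative_count`.
#' @examples
#' w <- matrix(0.5, 3, 3); diag(w) <- 0
#' g <- weighted_graph(w)
#' graph_density(g)
#' @export
weighted_graph <- function(weights, labels = NULL, tol = 1e-8) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("`weights` must be a numeric matrix", call. = FALSE)
  n <- nrow(weights)
  if (n != ncol(weights))
    stop("`weights` must be square, got ", n, " x ", ncol(weights),
         call. = FALSE)
  if (n < 2) stop("a graph needs at least 2 nodes", call. = FALSE)
  if (anyNA(weights)) stop("`weights` contains missing values", call. = FALSE)
  scale <- max(abs(weights), 1)
  if (max(abs(weights - t(weights))) > tol * scale)
    stop("`weights` is asymmetric beyond tolerance ", tol, call. = FALSE)
  w <- (weights + t(weights)) / 2
  diag(w) <- 0
  neg <- sum(w < 0)
  if (neg > 0) w[w < 0] <- 0
  if (is.null(labels)) labels <- rownames(weights)
  if (is.null(labels)) labels <- sprintf("ROI_%03d", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("`labels` length ", length(labels), " does not match ", n, " nodes",
         call. = FALSE)
  if (anyDuplicated(labels))
    stop("node labels must be unique", call. = FALSE)
  dimnames(w) <- list(labels, labels)
  structure(list(weights = w, labels = labels),
            negative_count = as.integer(neg),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("<weighted_graph> %d nodes, %d edges, density %.3f\n",
              n_nodes(x), n_edges(x), graph_density(x)))
  invisible(x)
}

#' Number of nodes / edges of a weighted graph
#' @param graph a `weighted_graph`.
#' @return integer count.
#' @export
n_nodes <- function(graph) length(graph$labels)

#' @rdname n_nodes
#' @export
n_edges <- function(graph) {
  sum(graph$weights[upper.tri(graph$weights)] > 0)
}

stopifnot_graph <- function(graph) {
  if (!inherits(graph, "weighted_graph"))
    stop("expected a `weighted_graph`", call. = FALSE)
  invisible(graph)
}

#' ROI label table
#'
#' Identity space for network nodes: region name, hemisphere and tissue
#' class, plus the atlas index of the parcel.
#'
#' @param region_name character, unique region identifiers.
#' @param hemisphere one of `"L"`, `"R"`, `"midline"` per region.
#' @param tissue_class one of `"cortical"`, `"subcortical"`, `"cerebellar"`.
#' @param atlas_index unique positive integers.
#' @return data.frame of class `roi_label_table`.
#' @export
roi_label_table <- function(region_name, hemisphere, tissue_class,
                            atlas_index = seq_along(region_name)) {
  region_name <- as.character(region_name)
  if (anyDuplicated(region_name)) stop("region names must be unique",
                                       call. = FALSE)
  hemisphere <- match.arg(as.character(hemisphere), c("L", "R", "midline"),
                          several.ok = TRUE)
  hemisphere <- rep_len(hemisphere, length(region_name))
  tissue_class <- match.arg(as.character(tissue_class),
                            c("cortical", "subcortical", "cerebellar"),
                            several.ok = TRUE)
  tissue_class <- rep_len(tissue_class, length(region_name))
  atlas_index <- as.integer(atlas_index)
  if (anyNA(atlas_index) || any(atlas_index < 1) || anyDuplicated(atlas_index))
    stop("`atlas_index` must be unique positive integers", call. = FALSE)
  structure(data.frame(region_name = region_name,
                       hemisphere = hemisphere,
                       tissue_class = tissue_class,
                       atlas_index = atlas_index,
                       stringsAsFactors = FALSE),
            class = c("roi_label_table", "data.frame"))
}

#' ROI time-series panel
#'
#' One subject x condition block of ROI time series: a T x N matrix with T
#' time points (rows) and N regions (columns). Constant columns are rejected
#' because they carry no correlation information.
#'
#' @param data numeric T x N matrix, T >= 3, no missing values.
#' @param subject_id,condition text identifiers.
#' @param roi_labels optional `roi_label_table`; its rows must match the
#'   panel columns.
#' @return object of class `roi_panel`.
#' @export
roi_panel <- function(data, subject_id = "S01", condition = "rest",
                      roi_labels = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix", call. = FALSE)
  if (nrow(data) < 3)
    stop("need at least 3 time points, got ", nrow(data), call. = FALSE)
  if (anyNA(data)) stop("panel contains missing values", call. = FALSE)
  v <- apply(data, 2, stats::var)
  if (any(v == 0))
    stop("constant (zero-variance) ROI columns: ",
         paste(which(v == 0), collapse = ", "), call. = FALSE)
  if (!is.null(roi_labels)) {
    if (!inherits(roi_labels, "roi_label_table"))
      stop("`roi_labels` must be a roi_label_table", call. = FALSE)
    if (nrow(roi_labels) != ncol(data))
      stop("label table has ", nrow(roi_labels), " rows but panel has ",
           ncol(data), " columns", call. = FALSE)
    colnames(data) <- roi_labels$region_name
  } else if (is.null(colnames(data))) {
    colnames(data) <- sprintf("ROI_%03d", seq_len(ncol(data)))
  }
  structure(list(subject_id = as.character(subject_id),
                 condition = as.character(condition),
                 data = data, roi_labels = roi_labels),
            class = "roi_panel")
}

#' @export
print.roi_panel <- function(x, ...) {
  cat(sprintf("<roi_panel> subject %s, condition %s: %d time points x %d ROIs\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Node-to-module partition
#'
#' A community affiliation vector in canonical form: module ids are the
#' integers `1..m` with no gaps, node #1 sits in module 1, and module ids
#' appear in order of first appearance along the node list. Any valid
#' grouping vector is canonicalized on construction.
#'
#' @param assignment integer-like vector of module ids, one per node.
#' @return object of class `node_partition`: list with `assignment`
#'   (canonical integer vector) and `m` (module count).
#' @examples
#' node_partition(c(2, 2, 1, 1))$assignment  # -> 1 1 2 2
#' @export
node_partition <- function(assignment) {
  a <- as.integer(round(as.numeric(assignment)))
  if (length(a) < 1 || anyNA(a))
    stop("invalid module assignment", call. = FALSE)
  a <- match(a, unique(a))  # first-appearance relabeling anchors node #1
  structure(list(assignment = a, m = max(a)), class = "node_partition")
}

#' @export
print.node_partition <- function(x, ...) {
  cat(sprintf("<node_partition> %d nodes in %d modules\n",
              length(x$assignment), x$m))
  invisible(x)
}

as_partition <- function(p, n = NULL) {
  if (!inherits(p, "node_partition")) p <- node_partition(p)
  if (!is.null(n) && length(p$assignment) != n)
    stop("partition covers ", length(p$assignment), " nodes, graph has ", n,
         call. = FALSE)
  p
}
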