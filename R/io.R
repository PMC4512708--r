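#' Read a square connectivity matrix from delimited text
#'
#' Accepts the canonical dialect (header row + header column of region
#' names) as well as headerless square numeric files, in which case a label
#' table must be supplied. The delimiter is inferred from the extension
#' (`.csv` = comma, otherwise tab/whitespace). The matrix is symmetrized by
#' averaging (asymmetries beyond `1e-8` relative are an error), the diagonal
#' is zeroed, and negative entries are clamped to zero with the count
#' recorded in the `negative_count` attribute of the result.
#'
#' @param path file path to a delimited text matrix.
#' @param labels optional `roi_label_table` (required for headerless files);
#'   when given, the file's region names must match it exactly.
#' @return a [weighted_graph()].
#' @export
read_matrix <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  first <- readLines(path, n = 1L)
  toks <- strsplit(first, if (sep == ",") "," else "[\t ]+")[[1]]
  toks <- toks[nzchar(toks)]
  has_header <- anyNA(suppressWarnings(as.numeric(toks)))
  if (has_header) {
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df)
    node_names <- colnames(m)
    if (!identical(rownames(m), node_names))
      stop("matrix file row names do not match column names", call. = FALSE)
  } else {
    m <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
    dimnames(m) <- NULL
    node_names <- NULL
  }
  if (!is.numeric(m))
    stop("matrix file contains non-numeric entries: ", path, call. = FALSE)
  if (nrow(m) != ncol(m))
    stop("matrix file is not square (", nrow(m), " x ", ncol(m), "): ", path,
         call. = FALSE)
  if (!is.null(labels)) {
    if (!inherits(labels, "roi_label_table"))
      stop("`labels` must be a roi_label_table", call. = FALSE)
    if (nrow(labels) != nrow(m))
      stop("label table has ", nrow(labels), " rows, matrix has ", nrow(m),
           call. = FALSE)
    if (!is.null(node_names) && !identical(node_names, labels$region_name))
      stop("matrix region names do not match the label table", call. = FALSE)
    node_names <- labels$region_name
  }
  if (is.null(node_names)) {
    if (is.null(labels))
      stop("headerless matrix needs a `labels` table: ", path, call. = FALSE)
  }
  weighted_graph(m, labels = node_names)
}

#' Write a weighted graph as delimited text
#'
#' Writes the canonical dialect (header row + header column of region
#' names); [read_matrix()] round-trips it.
#'
#' @param graph a `weighted_graph`.
#' @param path output path; `.csv` selects comma separation, anything else
#'   is tab-separated.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(graph, path) {
  stopifnot_graph(graph)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(region = graph$labels, graph$weights,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a node partition
#'
#' Partitions are stored as two-column delimited text (node label, module
#' id). Files whose module ids are not in canonical form (node #1 in module
#' 1, ids consecutive in order of first appearance) are canonicalized with a
#' warning.
#'
#' @param path file path.
#' @param labels optional character vector of expected node labels, in
#'   order; the file's nodes must match exactly.
#' @return [read_partition()] returns a `node_partition`;
#'   [write_partition()] returns `path` invisibly.
#' @export
read_partition <- function(path, labels = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("partition file needs (node, module) columns",
                         call. = FALSE)
  if (!is.null(labels)) {
    if (!identical(as.character(df[[1]]), as.character(labels)))
      stop("partition node labels do not match the expected labels",
           call. = FALSE)
  }
  raw <- as.integer(df[[2]])
  p <- node_partition(raw)
  if (!identical(p$assignment, raw))
    warning("partition was not canonical; relabeled with node #1 in module 1",
            call. = FALSE)
  names(p$assignment) <- as.character(df[[1]])
  p
}

#' @param partition a `node_partition` (or coercible assignment vector).
#' @param node_labels node names to write alongside the module ids.
#' @rdname read_partition
#' @export
write_partition <- function(partition, path, node_labels = NULL) {
  p <- as_partition(partition)
  if (is.null(node_labels)) node_labels <- names(p$assignment)
  if (is.null(node_labels))
    node_labels <- sprintf("ROI_%03d", seq_along(p$assignment))
  utils::write.table(
    data.frame(node = node_labels, module = p$assignment),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an ROI label table
#'
#' Tab-separated with columns `region_name`, `hemisphere`, `tissue_class`,
#' `atlas_index`.
#'
#' @param path file path.
#' @return [read_label_table()] returns a `roi_label_table`.
#' @export
read_label_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("region_name", "hemisphere", "tissue_class", "atlas_index")
  if (!all(need %in% names(df)))
    stop("label table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  roi_label_table(df$region_name, df$hemisphere, df$tissue_class,
                  df$atlas_index)
}

#' @param labels a `roi_label_table`.
#' @rdname read_label_table
#' @export
write_label_table <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
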