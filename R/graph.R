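#' Pairwise Euclidean distance matrix between patients
#'
#' @param features a `feature_matrix` or numeric matrix (rows = patients).
#' @return symmetric n x n distance matrix with zero diagonal.
#' @export
pairwise_euclidean <- function(features) {
  x <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  if (nrow(x) < 2L)
    stop_cohortgnn("need at least 2 patients for a distance matrix",
                   class = "cohortgnn_degenerate_error")
  if (anyNA(x))
    stop_cohortgnn("feature matrix contains missing values",
                   class = "cohortgnn_schema_error")
  d <- as.matrix(stats::dist(x, method = "euclidean"))
  dimnames(d) <- NULL
  d
}

#' Gaussian (RBF) similarity from a distance matrix
#'
#' Maps distances to similarities `s = exp(-d^2 / (2 sigma^2))`, so identical
#' profiles score 1 and similarity decays monotonically with distance. The
#' kernel is order-reversing, which is why the bandwidth does not affect the
#' percentile-thresholded edge set -- it matters only when similarities are
#' exported or inspected.
#'
#' @param d symmetric distance matrix.
#' @param bandwidth kernel scale sigma; either a positive number or
#'   `"median"` (the median of off-diagonal distances, the standard
#'   scale-free heuristic).
#' @return the similarity matrix with attribute `bandwidth` set to the value
#'   actually used.
#' @export
rbf_similarity <- function(d, bandwidth = "median") {
  d <- as.matrix(d)
  if (identical(bandwidth, "median")) {
    off <- d[upper.tri(d)]
    bandwidth <- stats::median(off)
  }
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0)
    stop_cohortgnn("bandwidth must be a positive scalar (or \"median\")",
                   class = "cohortgnn_parameter_error")
  s <- exp(-d^2 / (2 * bandwidth^2))
  attr(s, "bandwidth") <- bandwidth
  s
}

#' Sparsify a similarity matrix by percentile thresholding
#'
#' Computes the given percentile of the strictly-upper-triangular similarity
#' scores (candidate pairs only; the unit diagonal is excluded so that n
#' self-similarities of 1 cannot bias the cut) and keeps the unordered pairs
#' whose similarity is strictly greater than that threshold. The percentile
#' is an order statistic (the inverse empirical CDF, [stats::quantile()]
#' type 1): with all-distinct scores this retains at most the top 20% of
#' pair similarities at the default 80th percentile, and never more. Each
#' retained pair contributes two directed entries to the edge index; there
#' are no self-loops. Ties at the threshold are dropped (strict inequality).
#'
#' @param s symmetric similarity matrix with unit diagonal.
#' @param percentile retention percentile in \[0, 100\]; default 80.
#' @param bandwidth bandwidth recorded on `s` (optional, for provenance).
#' @param quantile_type percentile convention passed to [stats::quantile()];
#'   the default (type 1) guarantees the retained fraction never exceeds
#'   `1 - percentile/100`. Interpolating conventions (e.g. type 7) can
#'   overshoot by up to one rank.
#' @return a `similarity_graph`: list with `similarity`, `bandwidth`,
#'   `threshold`, `percentile`, `edge_index` (m x 2 integer matrix of
#'   directed source/target pairs, 1-based) and `n_nodes`.
#' @export
threshold_edges <- function(s, percentile = 80, bandwidth = NULL,
                            quantile_type = 1) {
  s <- as.matrix(s)
  n <- nrow(s)
  if (!isTRUE(all.equal(s, t(s), tolerance = 1e-12)))
    stop_cohortgnn("similarity matrix must be symmetric",
                   class = "cohortgnn_parameter_error")
  scores <- s[upper.tri(s)]
  threshold <- unname(stats::quantile(scores, percentile / 100,
                                      type = quantile_type))
  adj <- s > threshold
  diag(adj) <- FALSE
  if (!any(adj) && length(unique(scores)) == 1L)
    warning("all candidate-pair scores are equal; no edges retained under strict thresholding")
  idx <- which(adj, arr.ind = TRUE)
  edge_index <- cbind(source = as.integer(idx[, 1]),
                      target = as.integer(idx[, 2]))
  edge_index <- edge_index[order(edge_index[, 1], edge_index[, 2]), ,
                           drop = FALSE]
  structure(list(similarity = s,
                 bandwidth = bandwidth %||% attr(s, "bandwidth"),
                 threshold = threshold,
                 percentile = percentile,
                 edge_index = edge_index,
                 n_nodes = n),
            class = "similarity_graph")
}

#' Build the population graph in one call
#'
#' Distance matrix, RBF similarities and percentile thresholding composed,
#' as used when preparing inputs for the graph models.
#'
#' @inheritParams pairwise_euclidean
#' @inheritParams rbf_similarity
#' @inheritParams threshold_edges
#' @return a `similarity_graph`.
#' @export
build_graph <- function(features, percentile = 80, bandwidth = "median") {
  d <- pairwise_euclidean(features)
  s <- rbf_similarity(d, bandwidth)
  threshold_edges(s, percentile)
}

#' Summarise a population graph
#'
#' Reports the directed edge-entry count, the average degree (entries per
#' node) and the number of isolated nodes. Isolated patients are reported
#' but never removed from the dataset: they simply receive no neighbour
#' information during propagation.
#'
#' @param g a `similarity_graph`.
#' @return a `graph_summary` list: `n_nodes`, `n_edge_entries`, `avg_degree`,
#'   `n_isolated`.
#' @export
graph_summary <- function(g) {
  stopifnot(inherits(g, "similarity_graph"))
  m <- nrow(g$edge_index)
  connected <- unique(c(g$edge_index[, 1], g$edge_index[, 2]))
  structure(list(n_nodes = g$n_nodes,
                 n_edge_entries = m,
                 avg_degree = if (g$n_nodes > 0) m / g$n_nodes else 0,
                 n_isolated = g$n_nodes - length(connected)),
            class = "graph_summary")
}

#' @export
print.graph_summary <- function(x, ...) {
  cat(sprintf(
    "<graph_summary> %d nodes, %d directed edge entries, avg degree %.1f, %d isolated\n",
    x$n_nodes, x$n_edge_entries, x$avg_degree, x$n_isolated))
  invisible(x)
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf(
    "<similarity_graph> %d nodes, %d directed edge entries (percentile %g, threshold %.4f)\n",
    x$n_nodes, nrow(x$edge_index), x$percentile, x$threshold))
  invisible(x)
}

#' Export the directed edge list as a two-column TSV of node ids
#' @param g a `similarity_graph`.
#' @param path file path.
#' @param ids node ids (defaults to 1..n as character).
#' @export
write_edge_tsv <- function(g, path, ids = as.character(seq_len(g$n_nodes))) {
  df <- data.frame(source = ids[g$edge_index[, 1]],
                   target = ids[g$edge_index[, 2]])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
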