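#' Graph construction configuration
#'
#' @param power_fraction Retain sources whose mean-square power exceeds this
#'   fraction of the maximum (default 0.5, i.e. the 50%-of-max rule).
#' @param beta Edge threshold in `[0, 1)`: weights not exceeding `beta` are
#'   removed.  Default 0.3.
#' @param absolute_correlation Use `|r|` as the edge weight (default), which
#'   keeps weights in `[0, 1]` and the graph Laplacian positive
#'   semidefinite; `FALSE` keeps signed correlations.
#' @export
graph_build_config <- function(power_fraction = 0.5, beta = 0.3,
                               absolute_correlation = TRUE) {
  assert_scalar(power_fraction, "power_fraction",
                lower = .Machine$double.xmin, upper = 1)
  assert_scalar(beta, "beta", 0, 1 - .Machine$double.eps)
  structure(list(power_fraction = power_fraction, beta = beta,
                 absolute_correlation = absolute_correlation),
            class = "graph_build_config")
}

#' Select high-power sources as graph nodes
#'
#' Computes the temporal power of each source signal,
#' \eqn{P_j = \mathrm{mean}_t\, x_j(t)^2}, and keeps every source whose
#' power strictly exceeds `power_fraction` times the maximum; the maximizing
#' source is always kept.  Discarding low-power sources bounds the node
#' count and hence the classifier cost.
#'
#' @param signals Numeric matrix (`M x T`).
#' @param cfg A [graph_build_config()].
#' @return Sorted integer vector of retained row indices.
#' @export
select_active_sources <- function(signals, cfg = graph_build_config()) {
  signals <- as.matrix(signals)
  p <- rowMeans(signals^2)
  if (all(p == 0)) stop("all-zero signals: no source to select", call. = FALSE)
  keep <- which(p > cfg$power_fraction * max(p))
  sort(unique(c(which.max(p), keep)))
}

#' Pearson correlation edge weight between two source signals
#'
#' The sample correlation
#' \deqn{w_{ij} = \frac{\sum_t (x_{it} - \bar{x}_i)(x_{jt} - \bar{x}_j)}
#'   {\sqrt{\sum_t (x_{it} - \bar{x}_i)^2} \sqrt{\sum_t (x_{jt} - \bar{x}_j)^2}}.}
#'
#' @param xi,xj Numeric vectors of equal length with nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_weight <- function(xi, xj) {
  if (length(xi) != length(xj)) stop("series lengths differ")
  if (var(xi) == 0 || var(xj) == 0)
    stop("zero-variance series: edge weight undefined", call. = FALSE)
  as.numeric(cor(xi, xj))
}

#' Correlation adjacency matrix over node signals
#'
#' Off-diagonal entries are pairwise Pearson correlations of the node time
#' courses (absolute value by default so weights lie in `[0, 1]`); the
#' diagonal is zero (no self-loops).
#'
#' @param node_signals Matrix (`M_g x T`), one row per node.
#' @param cfg A [graph_build_config()].
#' @return Symmetric `M_g x M_g` matrix with zero diagonal.
#' @export
correlation_adjacency <- function(node_signals, cfg = graph_build_config()) {
  node_signals <- as.matrix(node_signals)
  if (nrow(node_signals) < 2L) stop("need at least 2 nodes", call. = FALSE)
  v <- apply(node_signals, 1L, var)
  if (any(v == 0))
    stop("zero-variance series: edge weight undefined", call. = FALSE)
  W <- cor(t(node_signals))
  if (cfg$absolute_correlation) W <- abs(W)
  diag(W) <- 0
  unname((W + t(W)) / 2)  # exact symmetry against rounding
}

#' Remove weak edges
#'
#' Keeps \eqn{W_{ij}} only where \eqn{W_{ij} > \beta}; otherwise the entry
#' is set to zero.  Symmetry is preserved and the operation is idempotent.
#' A warning is emitted when thresholding disconnects the graph (the
#' classifier still runs on a disconnected graph).
#'
#' @param W Symmetric adjacency matrix.
#' @param beta Threshold in `[0, 1)`.
#' @export
apply_edge_threshold <- function(W, beta) {
  assert_scalar(beta, "beta", 0, 1 - .Machine$double.eps)
  Wt <- W
  Wt[Wt <= beta] <- 0
  if (nrow(Wt) > 1L && !graph_is_connected(Wt))
    warning("edge threshold disconnects the graph", call. = FALSE)
  Wt
}

graph_is_connected <- function(W) {
  n <- nrow(W)
  reached <- logical(n); reached[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(W[frontier, , drop = FALSE] != 0) > 0 & !reached)
    reached[nxt] <- TRUE
    frontier <- nxt
  }
  all(reached)
}

#' Build a source graph from localized signals
#'
#' Full construction used by the pipeline: node selection by the
#' power-fraction rule, correlation edge weights, then `beta`-thresholding.
#'
#' @param signals Source signal matrix (`M x T`); rows indexed by `node_ids`
#'   if given.
#' @param cfg A [graph_build_config()].
#' @param node_ids Optional original source indices for the rows.
#' @param node_positions Optional 3-column matrix of node coordinates.
#' @return Object of class `source_graph`: `node_ids`, `node_positions`,
#'   `W`, `node_signals`.
#' @export
build_source_graph <- function(signals, cfg = graph_build_config(),
                               node_ids = NULL, node_positions = NULL) {
  signals <- as.matrix(signals)
  node_ids <- node_ids %||% seq_len(nrow(signals))
  keep <- select_active_sources(signals, cfg)
  sig <- signals[keep, , drop = FALSE]
  W <- apply_edge_threshold(correlation_adjacency(sig, cfg), cfg$beta)
  structure(list(node_ids = node_ids[keep],
                 node_positions = if (!is.null(node_positions))
                   node_positions[keep, , drop = FALSE],
                 W = W, node_signals = sig),
            class = "source_graph")
}

#' @export
print.source_graph <- function(x, ...) {
  cat(sprintf("<source_graph> %d nodes, %d edges\n", nrow(x$W),
              sum(x$W[upper.tri(x$W)] != 0)))
  invisible(x)
}

#' Merge per-epoch supports into a common node set
#'
#' The classifier needs one node set shared by all epochs.  Per-epoch
#' supports are merged by union and the union is re-ranked by mean source
#' power across epochs; optionally only the `max_nodes` strongest are kept.
#'
#' @param supports List of integer vectors (per-epoch supports).
#' @param power_by_source Optional numeric vector of mean power per source
#'   used for the ranking; defaults to inclusion frequency across epochs.
#' @param max_nodes Optional cap on the merged node count.
#' @return Sorted integer vector of source indices.
#' @export
merge_supports <- function(supports, power_by_source = NULL,
                           max_nodes = NULL) {
  u <- sort(unique(unlist(supports)))
  if (length(u) == 0L) stop("no support to merge", call. = FALSE)
  if (!is.null(max_nodes) && length(u) > max_nodes) {
    score <- if (!is.null(power_by_source)) power_by_source[u]
             else vapply(u, function(j) sum(vapply(supports, function(s)
               j %in% s, logical(1))), numeric(1))
    u <- sort(u[order(score, decreasing = TRUE)[seq_len(max_nodes)]])
  }
  u
}

#' Write a graph as a delimited edge list
#'
#' Three-column TSV (`from`, `to`, `weight`), upper triangle only.
#'
#' @param graph A `source_graph`.
#' @param path Output file path.
#' @export
write_graph_edgelist <- function(graph, path) {
  idx <- which(upper.tri(graph$W) & graph$W != 0, arr.ind = TRUE)
  df <- data.frame(from = graph$node_ids[idx[, 1L]],
                   to = graph$node_ids[idx[, 2L]],
                   weight = graph$W[idx])
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
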