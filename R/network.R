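#' Thresholded Pearson correlation graph
#'
#' Builds a sample-to-sample or gene-to-gene graph from an expression
#' matrix: nodes are the entries along `axis`, and an edge joins a pair
#' whose Pearson correlation (computed across the other axis) is at least
#' `threshold`. The threshold is applied to the signed correlation, so
#' anti-correlated pairs are never linked. Expression is log-transformed as
#' `log2(x + 1)` by default (recommended for TPM/CPM). Constant profiles
#' yield undefined correlations; such nodes are retained edgeless with a
#' warning.
#'
#' @param expr an [expression_matrix()] (genes x samples).
#' @param axis `"samples"` or `"genes"`.
#' @param threshold correlation threshold in `[-1, 1]`; co-expression
#'   analyses use high positive values (0.90-0.99).
#' @param log2_transform apply `log2(x + 1)` first (default `TRUE`).
#' @return a list of class `correlation_graph`: `nodes` (ordered labels),
#'   `edges` (data.frame `from`, `to`, `weight` with `from` before `to` in
#'   node order), `threshold`, `axis`.
#' @export
correlation_graph <- function(expr, axis = c("samples", "genes"), threshold,
                              log2_transform = TRUE) {
  axis <- match.arg(axis)
  if (threshold < -1 || threshold > 1) stop("threshold must be in [-1, 1]")
  y <- unclass(expr)
  attr(y, "unit") <- NULL
  if (log2_transform) y <- log2(y + 1)
  if (axis == "genes") y <- t(y)
  if (nrow(y) < 3L) {
    stop("need >= 3 observations along the correlated axis, got ", nrow(y))
  }
  nodes <- colnames(y)
  cm <- suppressWarnings(cor(y))
  if (anyNA(cm)) {
    n_const <- sum(apply(y, 2L, function(v) stats::sd(v) == 0))
    warning(n_const, " constant profile(s) have undefined correlations; ",
            "the corresponding nodes are kept without edges")
  }
  idx <- which(upper.tri(cm) & !is.na(cm) & cm >= threshold, arr.ind = TRUE)
  edges <- data.frame(from = nodes[idx[, 1L]], to = nodes[idx[, 2L]],
                      weight = cm[idx], stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 axis = axis),
            class = "correlation_graph")
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat(sprintf("correlation_graph (%s): %d nodes, %d edges at r >= %g\n",
              x$axis, length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

# symmetric sparse adjacency matrix of a correlation_graph
graph_adjacency <- function(graph) {
  n <- length(graph$nodes)
  i <- match(graph$edges$from, graph$nodes)
  j <- match(graph$edges$to, graph$nodes)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                       x = rep(graph$edges$weight, 2L),
                       dims = c(n, n), dimnames = list(graph$nodes, graph$nodes))
}

#' Markov Clustering (MCL) of a correlation graph
#'
#' From-scratch MCL: self-loops are added with weight equal to each node's
#' maximum incident edge weight (1 for isolated nodes), columns are
#' normalised to a stochastic matrix, then expansion (matrix squaring) and
#' inflation (elementwise power `inflation`, renormalise) alternate until
#' the largest entry change falls below `tol` or `max_iter` is reached
#' (non-convergence returns the current state with a warning). Entries
#' below `prune` are dropped each iteration for sparsity. Clusters are the
#' connected components of the limit matrix's nonzero pattern; they are
#' numbered 1..k by decreasing size, ties broken by the smallest member
#' label, so the result is invariant to node input order. MCL never merges
#' nodes from different connected components of the input graph.
#'
#' @param graph a [correlation_graph()].
#' @param inflation inflation exponent controlling granularity
#'   (default 2.2).
#' @param max_iter iteration cap (default 100).
#' @param tol convergence tolerance on the max entry change (default 1e-6).
#' @param prune entries below this are zeroed each iteration
#'   (default 1e-8).
#' @param min_size clusters smaller than this are flagged as small
#'   (default 3); they are still reported.
#' @return a list of class `mcl_clustering`: `membership` (named integer
#'   vector over all nodes), `sizes`, `small` (logical per cluster),
#'   `converged`, `iterations`.
#' @export
mcl_cluster <- function(graph, inflation = 2.2, max_iter = 100, tol = 1e-6,
                        prune = 1e-8, min_size = 3) {
  stopifnot(inherits(graph, "correlation_graph"))
  n <- length(graph$nodes)
  if (n == 0L) stop("graph has no nodes")
  if (inflation <= 1) stop("inflation must be > 1")
  adj <- graph_adjacency(graph)
  self <- apply(abs(adj), 1L, max)
  self[self == 0] <- 1
  m <- adj + Matrix::Diagonal(n, x = self)
  m <- col_normalize(m)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    m2 <- m %*% m                              # expansion
    m2 <- as(m2, "CsparseMatrix")
    m2@x <- m2@x^inflation                     # inflation
    m2 <- Matrix::drop0(m2, tol = prune)
    m2 <- col_normalize(m2)
    delta <- max(abs(m2 - m))
    m <- m2
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge in ", max_iter,
            " iterations; returning the current clustering")
  }
  g <- igraph::graph_from_adjacency_matrix(m != 0, mode = "max",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  names(comp) <- graph$nodes
  relabel_clusters(comp, min_size)
}

# columns of a sparse nonneg matrix scaled to sum 1 (zero columns get a
# self-loop to stay stochastic)
col_normalize <- function(m) {
  cs <- Matrix::colSums(m)
  zero <- cs == 0
  if (any(zero)) {
    m <- m + Matrix::Diagonal(ncol(m), x = as.numeric(zero))
    cs[zero] <- 1
  }
  m %*% Matrix::Diagonal(ncol(m), x = 1 / cs)
}

# renumber components by decreasing size, ties by smallest member label
relabel_clusters <- function(membership, min_size) {
  ids <- sort(unique(membership))
  size <- vapply(ids, function(k) sum(membership == k), integer(1))
  first <- vapply(ids, function(k) min(names(membership)[membership == k]),
                  character(1))
  ord <- order(-size, first)
  new <- match(membership, ids[ord])
  names(new) <- names(membership)
  sizes <- size[ord]
  names(sizes) <- seq_along(sizes)
  structure(list(membership = new, sizes = sizes,
                 small = sizes < min_size, min_size = min_size),
            class = "mcl_clustering")
}

#' @export
print.mcl_clustering <- function(x, ...) {
  cat(sprintf("mcl_clustering: %d nodes in %d clusters (%d below min size %d)\n",
              length(x$membership), length(x$sizes), sum(x$small), x$min_size))
  cat("sizes:", paste(utils::head(x$sizes, 10L), collapse = ", "),
      if (length(x$sizes) > 10L) "..." else "", "\n")
  invisible(x)
}

#' Export a correlation graph to GraphML
#'
#' Writes an attributed GraphML document (readable by igraph, Gephi,
#' Graphia and similar tools): node attributes are the cluster assignment
#' (if given) plus any metadata columns, edge attribute is the correlation
#' weight. The export round-trips losslessly through
#' [igraph::read_graph()].
#'
#' @param graph a [correlation_graph()].
#' @param path output file path.
#' @param clustering optional [mcl_cluster()] result covering the graph's
#'   nodes.
#' @param node_data optional data.frame of node metadata with a column
#'   matching node labels (first column used as the key).
#' @return `path`, invisibly.
#' @export
export_graphml <- function(graph, path, clustering = NULL, node_data = NULL) {
  stopifnot(inherits(graph, "correlation_graph"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(graph$nodes), name = graph$nodes)
  if (nrow(graph$edges) > 0L) {
    ends <- rbind(match(graph$edges$from, graph$nodes),
                  match(graph$edges$to, graph$nodes))
    g <- igraph::add_edges(g, as.vector(ends), weight = graph$edges$weight)
  }
  if (!is.null(clustering)) {
    memb <- clustering$membership[graph$nodes]
    if (anyNA(memb)) stop("clustering does not cover all graph nodes")
    g <- igraph::set_vertex_attr(g, "cluster", value = as.integer(memb))
  }
  if (!is.null(node_data)) {
    node_data <- as.data.frame(node_data, stringsAsFactors = FALSE)
    key <- match(graph$nodes, node_data[[1L]])
    for (cc in names(node_data)[-1L]) {
      g <- igraph::set_vertex_attr(g, cc, value = node_data[[cc]][key])
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
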