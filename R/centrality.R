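#' Five graph-centrality measures
#'
#' Implementations of the five node-centrality measures used to rank
#' proteins in QQPPI networks, on connected simple undirected graphs.
#' Scales are mixed on purpose, matching how the measures are reported
#' in the network-biology literature:
#' \describe{
#'   \item{degree}{raw neighbor count (integer).}
#'   \item{betweenness}{fraction of shortest paths through the node,
#'     normalized by `(n-1)(n-2)/2` unordered pairs, in \[0, 1\].}
#'   \item{closeness}{`(n-1) / sum of distances`, in (0, 1\].}
#'   \item{eigenvector}{component of the unit-Euclidean-norm principal
#'     eigenvector of the adjacency matrix (non-negative).}
#'   \item{centroid value}{signed integer: the worst pairwise
#'     "closeness contest" outcome against any other node.}
#' }
#'
#' @param graph a connected simple undirected igraph graph with named
#'   vertices.
#' @return named numeric (or integer) vector over the vertices.
#' @name centrality
NULL

# 0-based adjacency list for the C++ kernels
adj_list0 <- function(graph) {
  lapply(igraph::as_adj_list(graph, mode = "all"),
         function(v) as.integer(v) - 1L)
}

dist_matrix <- function(graph) {
  D <- bfs_distance_matrix(adj_list0(graph))
  if (anyNA(D)) stop("graph is disconnected", call. = FALSE)
  dimnames(D) <- list(igraph::V(graph)$name, igraph::V(graph)$name)
  D
}

#' @rdname centrality
#' @export
degree_centrality <- function(graph) {
  lengths(igraph::as_adj_list(graph, mode = "all"))
}

#' @rdname centrality
#' @export
betweenness_centrality <- function(graph) {
  n <- igraph::vcount(graph)
  nm <- igraph::V(graph)$name
  if (n < 3L) {
    warning("betweenness undefined for n < 3; returning zeros")
    out <- rep(0, n)
    names(out) <- nm
    return(out)
  }
  raw <- brandes_betweenness(adj_list0(graph)) / 2  # unordered pairs
  out <- raw / ((n - 1) * (n - 2) / 2)
  names(out) <- nm
  out
}

#' @rdname centrality
#' @export
closeness_centrality <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 2L) stop("closeness needs at least 2 nodes", call. = FALSE)
  D <- dist_matrix(graph)
  (n - 1) / rowSums(D)
}

#' @rdname centrality
#' @param tol power-iteration convergence threshold on the maximum
#'   successive-iterate difference.
#' @param max_iter iteration cap; non-convergence is an error carrying
#'   the residual.
#' @export
eigenvector_centrality <- function(graph, tol = 1e-12,
                                   max_iter = 10000L) {
  n <- igraph::vcount(graph)
  A <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  # power iteration on A + I: the shift keeps the dominant eigenvalue
  # strictly largest in magnitude, so bipartite graphs also converge
  x <- rep(1 / sqrt(n), n)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + x
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) < tol) {
      x <- y
      converged <- TRUE
      break
    }
    x <- y
  }
  if (!converged) {
    stop(sprintf(
      "power iteration did not converge in %d iterations (residual %.3e)",
      max_iter, max(abs(y - x))), call. = FALSE)
  }
  x <- abs(x)
  names(x) <- igraph::V(graph)$name
  x
}

#' @rdname centrality
#' @export
centroid_value <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 2L) stop("centroid value needs at least 2 nodes",
                   call. = FALSE)
  D <- dist_matrix(graph)
  out <- integer(n)
  for (v in seq_len(n)) {
    dv <- D[, v]
    # gamma_v(u) - gamma_u(v) for all u at once; ties count for neither
    f <- colSums(dv < D) - colSums(dv > D)
    out[v] <- as.integer(min(f[-v]))
  }
  names(out) <- igraph::V(graph)$name
  out
}

#' Compute all five centrality measures
#'
#' One row per node, columns ordered as conventionally tabulated:
#' degree, betweenness, closeness, centroid value, eigenvector.
#'
#' @param graph connected simple undirected igraph graph.
#' @param tol,max_iter eigenvector power-iteration controls.
#' @return `CentralityTable` data.frame sorted by node symbol.
#' @export
compute_all <- function(graph, tol = 1e-12, max_iter = 10000L) {
  nm <- igraph::V(graph)$name
  out <- data.frame(
    node = nm,
    degree = unname(degree_centrality(graph)[nm]),
    betweenness = unname(betweenness_centrality(graph)[nm]),
    closeness = unname(closeness_centrality(graph)[nm]),
    centroid_value = unname(centroid_value(graph)[nm]),
    eigenvector = unname(eigenvector_centrality(graph, tol = tol,
                                                max_iter = max_iter)[nm]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a centrality table as TSV
#'
#' @param table `CentralityTable` from [compute_all()].
#' @param path output TSV path.
#' @export
write_centrality <- function(table, path) {
  write_tsv(table, path)
}
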