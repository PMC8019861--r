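CENTRALITY_MEASURES <- c("degree", "betweenness", "closeness",
                         "centroid_value", "eigenvector")

#' Top-k node sets per centrality measure
#'
#' For each of the five measures, the nodes with the k highest values.
#' All nodes tied with the k-th value are included, which makes the
#' sets order-independent and deterministic; for the floating-point
#' eigenvector column, values within `eigen_tol` of the k-th value
#' count as tied.
#'
#' @param table `CentralityTable` from [compute_all()].
#' @param k list length per measure (before tie inclusion).
#' @param eigen_tol absolute near-tie tolerance for the eigenvector
#'   column.
#' @return named list (measure -> character vector of nodes), with
#'   attribute `k`.
#' @export
top_k_per_measure <- function(table, k = 30L, eigen_tol = 1e-12) {
  if (k < 1L) stop("'k' must be >= 1", call. = FALSE)
  if (nrow(table) == 0L) stop("empty centrality table", call. = FALSE)
  out <- lapply(CENTRALITY_MEASURES, function(m) {
    v <- table[[m]]
    kth <- sort(v, decreasing = TRUE)[min(k, length(v))]
    thr <- if (m == "eigenvector") kth - eigen_tol else kth
    sort(table$node[v >= thr])
  })
  names(out) <- CENTRALITY_MEASURES
  attr(out, "k") <- as.integer(k)
  out
}

#' Consensus selection of central nodes
#'
#' A node is kept when it appears in at least `min_measures` of the
#' per-measure top lists — the "more central" rule that a protein is a
#' key molecule only if several independent centrality notions agree
#' on it.
#'
#' @param top_sets list from [top_k_per_measure()].
#' @param min_measures minimum number of supporting measures
#'   (1 to `length(top_sets)`).
#' @return object of class `consensus_selection`: `top_sets`,
#'   `consensus` (data.frame node / n_measures / which_measures sorted
#'   by count descending then symbol), `k`, `min_measures`.
#' @export
consensus_central <- function(top_sets, min_measures = 2L) {
  min_measures <- as.integer(min_measures)
  if (min_measures < 1L || min_measures > length(top_sets)) {
    stop("'min_measures' must lie in 1..number of measures",
         call. = FALSE)
  }
  membership <- lapply(names(top_sets), function(m) {
    data.frame(node = top_sets[[m]], measure = m,
               stringsAsFactors = FALSE)
  })
  mem <- do.call(rbind, membership)
  counts <- table(mem$node)
  keep <- names(counts)[counts >= min_measures]
  which_measures <- vapply(keep, function(nd) {
    paste(names(top_sets)[vapply(top_sets, function(s) nd %in% s,
                                 logical(1))],
          collapse = ",")
  }, character(1))
  consensus <- data.frame(
    node = keep,
    n_measures = as.integer(counts[keep]),
    which_measures = unname(which_measures),
    stringsAsFactors = FALSE
  )
  consensus <- consensus[order(-consensus$n_measures, consensus$node),
                         , drop = FALSE]
  rownames(consensus) <- NULL
  structure(list(top_sets = top_sets, consensus = consensus,
                 k = attr(top_sets, "k"),
                 min_measures = min_measures),
            class = "consensus_selection")
}

#' @export
print.consensus_selection <- function(x, ...) {
  cat(sprintf(
    "consensus_selection: %d node(s) in >= %d of %d top-%s lists\n",
    nrow(x$consensus), x$min_measures, length(x$top_sets),
    x$k %||% "?"))
  invisible(x)
}

#' Write prioritization tables
#'
#' One TSV of per-measure top lists (long form: measure, node) and one
#' consensus TSV (node, n_measures, which_measures).
#'
#' @param selection a `consensus_selection`.
#' @param top_path,consensus_path output TSV paths.
#' @export
write_consensus <- function(selection, top_path, consensus_path) {
  stopifnot(inherits(selection, "consensus_selection"))
  long <- do.call(rbind, lapply(names(selection$top_sets), function(m) {
    data.frame(measure = m, node = selection$top_sets[[m]],
               stringsAsFactors = FALSE)
  }))
  write_tsv(long, top_path)
  write_tsv(selection$consensus, consensus_path)
  invisible(c(top_path, consensus_path))
}
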