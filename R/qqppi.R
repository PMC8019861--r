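#' Extract the query-query PPI network
#'
#' Induced subgraph of the interactome on the query genes (here, the
#' differentially expressed genes): nodes are queries found in the
#' interactome, edges are the interactome edges with both endpoints in
#' that set. Up/down direction annotations are attached for reporting;
#' they play no role in centrality or prioritization. Queries absent
#' from the interactome are counted.
#'
#' @param interactome igraph graph with gene-symbol vertex names.
#' @param degs `DEGTable` data.frame (columns gene, direction) or a
#'   character vector of query symbols.
#' @return object of class `qqppi_network`: `graph` (induced igraph
#'   with `direction` vertex attribute), `analysis_component`
#'   (vertex names of the largest connected component; ties broken by
#'   the component holding the lexicographically smallest symbol) and
#'   `n_queries_unmapped`.
#' @export
extract_qqppi <- function(interactome, degs) {
  if (igraph::vcount(interactome) == 0L) {
    stop("empty interactome", call. = FALSE)
  }
  if (is.character(degs)) {
    degs <- data.frame(gene = degs, direction = NA_character_,
                       stringsAsFactors = FALSE)
  }
  if (nrow(degs) == 0L) stop("empty query table", call. = FALSE)
  degs <- degs[!duplicated(degs$gene), , drop = FALSE]
  queries <- degs$gene
  present <- intersect(queries, igraph::V(interactome)$name)
  if (length(present) == 0L) {
    stop("zero queries found in the interactome", call. = FALSE)
  }
  sub <- igraph::induced_subgraph(interactome, present)
  dir_lut <- degs$direction
  names(dir_lut) <- degs$gene
  igraph::V(sub)$direction <- unname(dir_lut[igraph::V(sub)$name])
  structure(
    list(graph = sub,
         analysis_component = lcc_members(sub),
         n_queries_unmapped = length(queries) - length(present)),
    class = "qqppi_network")
}

# names of the maximum-cardinality component; ties resolved in favor of
# the component containing the smallest symbol
lcc_members <- function(graph) {
  comp <- igraph::components(graph)
  sizes <- comp$csize
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1L) {
    firsts <- vapply(biggest, function(ci) {
      min(igraph::V(graph)$name[comp$membership == ci])
    }, character(1))
    biggest <- biggest[order(firsts)[1L]]
  }
  sort(igraph::V(graph)$name[comp$membership == biggest])
}

#' Restrict a QQPPI network to its largest connected component
#'
#' The distance-based centralities (closeness, centroid value) are only
#' defined on connected graphs, so rankings are computed on the largest
#' component; nodes outside it never enter the analysis.
#'
#' @param network a `qqppi_network`.
#' @return a `qqppi_network` induced on the analysis component, with the
#'   number of excluded nodes in `n_excluded`.
#' @export
largest_component <- function(network) {
  stopifnot(inherits(network, "qqppi_network"))
  keep <- network$analysis_component
  sub <- igraph::induced_subgraph(network$graph, keep)
  structure(
    list(graph = sub,
         analysis_component = sort(igraph::V(sub)$name),
         n_queries_unmapped = network$n_queries_unmapped,
         n_excluded = igraph::vcount(network$graph) - length(keep)),
    class = "qqppi_network")
}

#' @export
print.qqppi_network <- function(x, ...) {
  cat(sprintf(
    "qqppi_network: %d nodes, %d edges; analysis component %d nodes; %d queries unmapped\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph),
    length(x$analysis_component), x$n_queries_unmapped))
  invisible(x)
}

#' Write QQPPI edge and node-attribute tables
#'
#' Edge TSV (`symbol_a`, `symbol_b`) plus a node TSV with the up/down
#' direction annotation and analysis-component membership.
#'
#' @param network a `qqppi_network`.
#' @param edges_path,nodes_path output TSV paths.
#' @export
write_qqppi <- function(network, edges_path, nodes_path) {
  stopifnot(inherits(network, "qqppi_network"))
  write_edge_tsv(network$graph, edges_path)
  nm <- igraph::V(network$graph)$name
  df <- data.frame(
    symbol = nm,
    direction = igraph::V(network$graph)$direction %||%
      rep(NA_character_, length(nm)),
    in_analysis_component = nm %in% network$analysis_component,
    stringsAsFactors = FALSE)
  df <- df[order(df$symbol), , drop = FALSE]
  write_tsv(df, nodes_path)
  invisible(c(edges_path, nodes_path))
}
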