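#!/usr/bin/env Rscript
# Stage 3: project the DEG list onto the interactome to form the
# query-query PPI (QQPPI) network — the induced subgraph whose nodes
# are differentially expressed genes and whose edges are their direct
# interactions — reduce it to the largest connected component, and
# compute the five centrality measures (degree, betweenness,
# closeness, centroid value, eigenvector) for every node.

library(netprio)

interactome <- read_edge_tsv("results/synthetic/interactome_edges.tsv")
degs <- read.delim("results/differential_expression/degs.tsv")

out <- "results/network"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

qq <- extract_qqppi(interactome, degs)
message(sprintf(
  "QQPPI: %d nodes / %d edges (edge/node ratio %.2f); %d queries not in interactome",
  igraph::vcount(qq$graph), igraph::ecount(qq$graph),
  igraph::ecount(qq$graph) / igraph::vcount(qq$graph),
  qq$n_queries_unmapped))
write_qqppi(qq, file.path(out, "qqppi_edges.tsv"),
            file.path(out, "qqppi_nodes.tsv"))

lcc <- largest_component(qq)
message(sprintf("analysis component: %d nodes (%d excluded)",
                igraph::vcount(lcc$graph), lcc$n_excluded))

cent <- compute_all(lcc$graph)
write_centrality(cent, file.path(out, "centrality.tsv"))
top5 <- cent[order(-cent$degree), ][1:5, ]
message("highest-degree nodes:")
for (i in 1:5) {
  message(sprintf(
    "  %s  degree %d  betweenness %.4f  closeness %.4f  centroid %d  eigenvector %.4f",
    top5$node[i], top5$degree[i], top5$betweenness[i],
    top5$closeness[i], top5$centroid_value[i], top5$eigenvector[i]))
}
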