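#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study that stands in for the real
# two-group expression + interactome inputs: a 43-case / 24-control
# expression matrix with a planted DEG fraction, a scale-free
# interactome with 5 planted hub genes, and a drug-target table biased
# toward high-degree genes. All later stages read the files written
# here, so the whole analysis is reproducible from one seed.

library(netprio)

cfg <- synth_config(
  n_genes = 1000, n_case = 43, n_control = 24,
  deg_fraction = 0.8,     # dense DEG fraction keeps the QQPPI connected
  effect_size = 3, noise_sd = 1,
  interactome_nodes = 1000, attachment_edges = 2,
  n_planted_hubs = 5, hub_extra_degree = 40,
  n_drugs = 20, hub_bias = 2,
  seed = 1
)

study <- run_synthetic_study(cfg)
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

write_expression(study$expression,
                 file.path(out, "expression.tsv"),
                 file.path(out, "sample_groups.tsv"))
write_edge_tsv(study$interactome, file.path(out, "interactome_edges.tsv"))
write_psimitab(study$interactome, file.path(out, "interactome.mitab"))
netprio:::write_tsv(
  data.frame(gene = study$truth$true_deg_genes,
             direction = unname(study$truth$true_directions),
             is_planted_hub = study$truth$true_deg_genes %in% study$hubs),
  file.path(out, "truth_degs.tsv"))
netprio:::write_tsv(study$drug_table, file.path(out, "drug_table.tsv"))

message(sprintf(
  "simulated %d genes x %d samples; interactome %d nodes / %d edges",
  nrow(study$expression$values), ncol(study$expression$values),
  igraph::vcount(study$interactome), igraph::ecount(study$interactome)))
message(sprintf("planted hubs: %s", paste(study$hubs, collapse = ", ")))
message(sprintf("planted DEGs: %d (%d up / %d down)",
                length(study$truth$true_deg_genes),
                sum(study$truth$true_directions == "up"),
                sum(study$truth$true_directions == "down")))
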