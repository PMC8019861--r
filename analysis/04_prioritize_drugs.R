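#!/usr/bin/env Rscript
# Stage 4: consensus prioritization and drug mapping. Nodes in the
# top-30 of at least two of the five centrality measures form the
# consensus central set; that set is joined against (a) the synthetic
# drug-target table and (b) the packaged curated drug-target table,
# keeping approved / experimental / investigational drugs.

library(netprio)

cent <- read.delim("results/network/centrality.tsv")
truth <- read.delim("results/synthetic/truth_degs.tsv")
out <- "results/prioritization"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sel <- consensus_central(top_k_per_measure(cent, k = 30),
                         min_measures = 2)
write_consensus(sel, file.path(out, "top_sets.tsv"),
                file.path(out, "consensus.tsv"))
hubs <- truth$gene[truth$is_planted_hub]
message(sprintf("consensus: %d central nodes; recovers %d / %d planted hubs",
                nrow(sel$consensus), sum(hubs %in% sel$consensus$node),
                length(hubs)))

# (a) synthetic drug table generated with the study
synth_drugs <- read_drug_table("results/synthetic/drug_table.tsv")
mapped <- map_drugs(sel, synth_drugs)
netprio:::write_tsv(mapped, file.path(out, "prioritized_drugs.tsv"))
message(sprintf("synthetic drug table: %d drug-target pairs over %d targets",
                nrow(mapped), length(unique(mapped$gene))))

# (b) curated table shipped with the package: overall summary
curated <- read_drug_table(system.file("extdata",
                                       "table2_drug_targets.tsv",
                                       package = "netprio"))
s <- drug_summary(curated)
message(sprintf(
  "curated drug-target table: %d distinct drugs over %d distinct targets",
  s$n_unique_drugs, s$n_unique_targets))
netprio:::write_tsv(
  data.frame(drug_name = names(s$per_drug_targets),
             n_targets = unname(s$per_drug_targets)),
  file.path(out, "curated_drug_summary.tsv"))
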