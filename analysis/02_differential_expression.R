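#!/usr/bin/env Rscript
# Stage 2: call differentially expressed genes from the simulated
# expression matrix by both statistical routes — per-gene one-way
# ANOVA on the raw p (the route used for PBMC-style data) and the
# median-split Fisher exact test with Benjamini-Hochberg correction
# (the count-based route used for islet-style data) — and compare
# them against the planted truth.

library(netprio)

expr <- read_expression("results/synthetic/expression.tsv",
                        "results/synthetic/sample_groups.tsv",
                        platform = "synthetic")
truth <- read.delim("results/synthetic/truth_degs.tsv")

out <- "results/differential_expression"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (route in c("anova", "fisher_bh")) {
  degs <- call_degs(expr, alpha = 0.05, route = route)
  netprio:::write_tsv(degs, file.path(out, paste0("degs_", route, ".tsv")))
  recall <- mean(truth$gene %in% degs$gene)
  fp <- sum(!(degs$gene %in% truth$gene))
  message(sprintf(
    "%s route: %d DEGs (%d up / %d down); recall of planted truth %.1f%%; %d false positives",
    route, nrow(degs), sum(degs$direction == "up"),
    sum(degs$direction == "down"), 100 * recall, fp))
}

# the ANOVA route feeds the network stages downstream
invisible(file.copy(file.path(out, "degs_anova.tsv"),
                    file.path(out, "degs.tsv"), overwrite = TRUE))
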