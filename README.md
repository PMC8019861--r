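# netprio

Network-based prioritization of drug targets from two-group gene
expression data and a protein–protein interaction (PPI) network.

## The problem

In complex diseases such as type 1 diabetes, hundreds to thousands of
genes change expression between patients and controls, far too many to
nominate as drug targets one by one. A standard systems-biology
strategy is to project the differentially expressed genes (DEGs) onto
the interactome and ask which of them occupy *topologically central*
positions among the disease-perturbed proteins: well-connected proteins
(hubs) and information-flow chokepoints (bottlenecks) are more likely
to matter functionally, and more likely to be druggable leverage
points. `netprio` implements this strategy end to end, for
bioinformaticians who have a normalized expression matrix with
case/control labels, an interactome in PSI-MITAB or edge-list form, and
a drug-target table.

## The method

1. **Differential expression.** Two routes:
   per-gene one-way fixed-effects ANOVA (for two groups,
   `F = SSB/MSW` on (1, n−2) df, equal to the squared pooled t
   statistic), thresholded on the raw p; or a median-split
   two-sided Fisher exact test per gene with Benjamini–Hochberg
   correction, thresholded on the adjusted p. A minimum-p merge
   combines p-values for genes measured on several array platforms.
2. **QQPPI extraction.** The query-query PPI network is the induced
   subgraph of the interactome on the DEGs: only query proteins, only
   their direct interactions. Distance-based measures need a connected
   graph, so analysis proceeds on the largest connected component.
3. **Five centralities**, computed from scratch on the unweighted
   simple graph (n nodes):
   - degree: `deg(v)`, the neighbor count;
   - betweenness: `Σ_{s<t} σ_st(v)/σ_st` over pairs `s ≠ t ≠ v`,
     normalized by `(n−1)(n−2)/2` (Brandes' accumulation over
     all-pairs BFS);
   - closeness: `(n−1) / Σ_u d(v,u)`;
   - eigenvector: component of the unit-norm principal eigenvector of
     the adjacency matrix (power iteration on `A + I`);
   - centroid value: `min_{u≠v} [γ_v(u) − γ_u(v)]`, where `γ_v(u)`
     counts nodes strictly closer to `v` than to `u` — the worst
     outcome of `v`'s pairwise "closeness contests".
4. **Consensus.** Take the top-k (default 30, ties included) nodes per
   measure; a protein is *consensus central* when it appears in at
   least `min_measures` (default 2) of the five lists.
5. **Drug mapping.** Consensus proteins are joined against a
   drug-target table (gene, drug, action, development group) filtered
   to approved / experimental / investigational drugs, yielding
   prioritized drug-target pairs. A curated 25-row drug-target table
   over 14 immune/islet-relevant targets ships with the package.

A seeded synthetic-study generator (preferential-attachment
interactome with planted hubs, two-group expression with planted
effects, degree-biased drug table) makes the full pipeline testable
offline, with known ground truth.

## Worked example

The `analysis/` directory is a numbered workflow over the package; run
the scripts in order from the repository root:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_network_centrality.R
Rscript analysis/04_prioritize_drugs.R
Rscript analysis/05_hub_recovery.R
```

Output of a full run (seed 1, as configured in the scripts):

```
simulated 1000 genes x 67 samples; interactome 1000 nodes / 2196 edges
planted hubs: G0416, G0710, G0774, G0853, G0975
planted DEGs: 800 (400 up / 400 down)
anova route: 818 DEGs (409 up / 409 down); recall of planted truth 100.0%; 18 false positives
fisher_bh route: 806 DEGs (403 up / 403 down); recall of planted truth 100.0%; 6 false positives
QQPPI: 818 nodes / 1596 edges (edge/node ratio 1.95); 0 queries not in interactome
analysis component: 806 nodes (12 excluded)
consensus: 36 central nodes; recovers 5 / 5 planted hubs
synthetic drug table: 34 drug-target pairs over 18 targets
curated drug-target table: 21 distinct drugs over 14 distinct targets
replicates with >= 4/5 hubs recovered: 50 / 50 (100%)
```

Reading it: with a 43-vs-24 design and a 3-unit planted shift the
ANOVA route recovers every planted DEG at a ~2% false-positive rate;
the QQPPI network keeps an edge/node ratio near 2, typical of
disease-gene subnetworks; all five planted hubs land in the consensus
central set, which then maps to 34 candidate drug–target pairs in the
synthetic drug table. The same pipeline runs unchanged on real inputs
via `pipeline_config(expression_file=, groups_file=, mitab_files=,
drug_table_file=)` and `run_pipeline()`.

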