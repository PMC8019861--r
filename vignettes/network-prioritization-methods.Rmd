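---
title: "Methods: network-based drug-target prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based drug-target prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netprio)
```

# Overview

`netprio` prioritizes drug targets by combining three kinds of
evidence: differential expression between disease and control samples,
position in the protein–protein interaction (PPI) network restricted
to the disease-perturbed proteins, and membership in a drug-target
table. This vignette documents the statistical model behind each
stage, the tunable parameters and their defaults, the numerical
choices, what the synthetic-data generator does and does not emulate,
and the known limitations.

# Differential expression

The expression container holds a normalized, log-scale gene × sample
matrix with a `case`/`control` label per sample. Missing values are
rejected at load time: imputation strategies are study-specific and
silently imputing would change downstream p-values, so missing-data
handling is deliberately left to the user as a pre-filter.

**ANOVA route.** For each gene, a one-way fixed-effects ANOVA over the
two groups: $F = \mathrm{SSB}/\mathrm{MSW}$ with $(1, n-2)$ degrees of
freedom, where SSB is the between-group sum of squares and MSW the
pooled within-group mean square. For two groups this $F$ is exactly
the square of the pooled-variance $t$ statistic — an identity the test
suite checks to $10^{-10}$. The route thresholds the *raw* p-value at
`alpha` (default 0.05); the BH-adjusted p is reported alongside for
the user. The per-gene computation is vectorized row-wise (one pass of
group means and sums of squares over the matrix) rather than fitted as
$n_{\text{genes}}$ separate linear models, which is the standard
approach for array-scale data.

**Fisher route.** The count-based route tests, per gene, a 2×2 table
of group × expression level and thresholds the Benjamini–Hochberg
adjusted p at `alpha`. How the 2×2 table is built from continuous
expression is genuinely open; this package adopts a **median split**:
a sample counts as "high" when the gene's value strictly exceeds the
gene's overall median, ties falling in the below-or-equal cell. This
is an interpretation, stated prominently here, and the route is
pluggable: `call_degs_from_tables()` accepts per-gene 2×2 tables built
any other way (e.g. from detection calls). The two-sided Fisher p is
the sum of hypergeometric probabilities of all tables with the same
margins whose probability does not exceed the observed table's (with
the conventional `1 + 1e-7` relative tolerance on the comparison);
the implementation delegates to `stats::fisher.test`, and an
enumeration oracle in the tests verifies every table with total
$\le 24$.

**Direction** is `up` iff the case mean exceeds the control mean, in
both routes — also for the Fisher route, where the table itself is
sign-free, so that reported directions are always comparable.

**Multi-platform studies.** When genes are measured on several
platforms, `min_p_across_platforms()` keeps the per-gene minimum p.
This is the permissive convention (it inflates significance slightly
and is not a meta-analysis); it is provided because it matches how
two-chip array designs are commonly merged.

**Degenerate genes** (constant across all samples) carry no two-group
information; they are reported as non-significant and counted in a
warning rather than dropped silently.

# QQPPI extraction

The query-query PPI network is the induced subgraph of the interactome
on the query (DEG) set: query proteins as nodes, their direct
interactions as edges. Queries absent from the interactome are counted
and reported, not an error — coverage of interactomes is far from
complete. Up/down annotations are carried on the nodes for export and
coloring only; they play no role in centrality or prioritization.

Closeness and centroid value are undefined on disconnected graphs, so
centralities are computed on the **largest connected component**
(ties broken toward the component containing the lexicographically
smallest symbol, making the choice deterministic). Nodes outside the
component never enter the rankings. Whether to analyse the full QQPPI
or its LCC is a genuine design fork — published centrality tools
differ — and restricting to the LCC is this package's documented
choice; `use_lcc = FALSE` is available for graphs known to be
connected.

# The five centrality measures

All measures treat the graph as simple, undirected and unweighted
(self-loops are removed at interactome construction; edge weights, if
present, are ignored). Scales follow the mixed conventions in which
these measures are tabulated in the network-biology literature:

| measure | definition | scale |
|---|---|---|
| degree | neighbor count | raw integer |
| betweenness | $\sum_{s<t}\sigma_{st}(v)/\sigma_{st}$, pairs $s\neq t\neq v$ | divided by $(n-1)(n-2)/2$, in $[0,1]$ |
| closeness | $(n-1)/\sum_u d(v,u)$ | in $(0,1]$ |
| eigenvector | principal eigenvector component | unit Euclidean norm, $\ge 0$ |
| centroid value | $\min_{u\neq v} f(v,u)$ | raw signed integer in $[-(n-1), n-2]$ |

Betweenness uses Brandes' dependency-accumulation algorithm over
all-pairs BFS (compiled); closeness and centroid value reuse the BFS
distance matrix.

**Centroid value.** $f(v,u) = \gamma_v(u) - \gamma_u(v)$ where
$\gamma_v(u)$ counts nodes $w$ (including $v$ and $u$ themselves) with
$d(w,v) < d(w,u)$; ties contribute to neither side. The inclusion of
the endpoints — $v$ always wins itself since $d(v,v)=0$ — follows the
published definition implemented by the standard centrality tools.
The prose definitions circulating in the literature are ambiguous on
this point, so the convention is locked by a brute-force
$O(n^3)$ γ-table oracle in the test suite, which also checks the
antisymmetry $f(v,u) = -f(u,v)$.

**Eigenvector.** Power iteration on $A + I$ from the uniform positive
start vector, normalized to unit Euclidean norm each step, stopping
when the maximum successive-iterate difference falls below `tol`
(default $10^{-12}$, `max_iter` 10 000; non-convergence is an error
carrying the residual). The identity shift moves the spectrum to
$\lambda_i + 1$, making the dominant eigenvalue strictly largest in
magnitude also on bipartite graphs (where $\pm\lambda_1$ would
otherwise tie and plain power iteration oscillates); it leaves the
eigenvectors unchanged. Star graphs — bipartite — exercise this path
in the tests.

# Consensus prioritization

Per measure, the top `k` nodes (default 30) are taken, **including
every node tied with the k-th value** — a policy the common prose
statement of the rule leaves open, chosen here because it makes the
selection order-independent and deterministic. For the eigenvector column, values within $10^{-12}$
of the k-th value count as tied, so float noise cannot reorder
near-equal components across platforms. A node is consensus central
when it appears in at least `min_measures` (default 2) of the five
lists. The rule is a set intersection count, not a weighted rank
aggregation — deliberately, to match the established "at least two
high centrality parameters" practice; Borda-style aggregation is a
non-goal.

# Drug mapping

The drug-target table schema is gene / drug id / drug name / action /
development groups (comma-separated tokens from approved,
experimental, investigational). Drugs are keyed by normalized drug
*name*, because curated tables repeat accession identifiers across
target rows; combination entries are kept verbatim as single drugs.
`map_drugs()` joins consensus genes to records whose group set
intersects the allowed groups (default: all three), omits genes with
no surviving drug, and sorts by measure support then gene. The
packaged curated table (25 rows, 21 distinct drugs, 14 targets,
checksum-locked in the tests) provides a realistic fixture and a
worked example; a manual literature-verification step, as practiced
in curation workflows, is representable only as a user-supplied
keep-list and is never computed.

# The synthetic-study generator

The generator exists so that every stage is testable offline with
known ground truth. One master integer seed drives all four
sub-generators through a fixed derivation (interactome: `seed`; hub
planting: `seed + 1`; expression: `seed + 2`; drugs: `seed + 3`), so
stages can be regenerated independently and byte-identical reruns are
guaranteed.

**Interactome.** Preferential attachment: `attachment_edges = m` new
edges per incoming node, giving exactly $(n-m)\,m$ edges, connected
and simple by construction. This emulates the approximately
scale-free, hub-dominated degree structure of real PPI networks; any
connected generator with heavy-tailed degrees could substitute. With
$m = 2$ and $m = 3$ the edge/node ratio is close to 2 and 3, bracketing
the ratios observed in real disease QQPPI networks (≈1.9 and ≈2.6).

**Expression.** Entry = gene baseline (Normal(7, 1), a typical log2
array intensity scale) + group shift + Normal(0, `noise_sd`) noise.
Defaults mirror the emulated study design: 43 cases vs 24 controls,
`deg_fraction = 0.1`, `effect_size = 2`, `noise_sd = 1` — at which a
two-group comparison with these group sizes has power ≈ 1, so planted
DEGs are recoverable and recovery failures indicate bugs, not noise.
Planted DEGs are split half up / half down by default (real studies
report mildly asymmetric up/down splits; the fraction is a parameter,
not hard-coded). Planted interactome hubs are always included in the
true-DEG set: the hubs exist as recovery targets for the
network stages, and a hub that fails the expression filter would
vanish from the QQPPI for reasons unrelated to the property under
test.

What the generator does **not** emulate: probe-level array structure,
platform effects, normalization artifacts, correlated genes
(co-expression), expression-dependent variance, or any coupling
between a gene's expression change and its network position. Passing
tests therefore demonstrate that the pipeline's logic is correct under
its stated assumptions — not that the statistical routes are robust to
real microarray pathologies.

**Hub planting** adds `extra_degree` edges from each chosen hub to
random non-neighbors outside the hub set, so every hub's degree rises
by exactly `extra_degree` (hub-hub edges would make the increment
unpredictable). Hubs are drawn uniformly among nodes with enough
non-neighbors; impossible requests error rather than silently adding
fewer edges.

**Drug table.** Targets are sampled per drug with probability
$\propto \mathrm{degree}^{\texttt{hub\_bias}}$ (default 2; 0 recovers
uniform sampling), 1–4 targets per drug, development groups drawn from
the approved/experimental/investigational combinations with weights
favoring approved drugs, emulating the composition of curated tables.

# Problem sizes and replication counts

The shipped analysis scripts and tests use a 1000-gene /
1000-node study with a dense (0.8) DEG fraction for pipeline-level
work, and 500-node graphs with 5 planted hubs (40 extra edges) × 50
seeded replicates for the hub-recovery study; statistical
calibration uses 2000-gene null matrices. These sizes are chosen so
the full workflow replays in about a minute on a laptop while the
QQPPI networks stay in the size regime (hundreds of nodes, edge/node
ratio ≈ 2) where the method is meant to operate. The dense DEG
fraction in the pipeline-level configuration matters: the induced
subgraph of a sparse (≈10%) node sample of a preferential-attachment
graph fragments into small components, and no centrality analysis on
its LCC can see the planted hubs. That is a property of induced
subgraphs of scale-free graphs, not of this implementation; real
disease QQPPI networks with thousands of DEGs sit comfortably in the
connected regime.

# Numerical and degenerate-input choices

- Betweenness on $n < 3$ nodes is all zeros (with a warning): no pair
  has an interior node. Closeness and centroid error on disconnected
  input — the caller must pass the LCC.
- ANOVA with both groups constant: equal constants give $F = 0$,
  $p = 1$; different constants give the $p \to 0$ limit; both warned.
- p-values entering `bh_adjust` must lie in $(0,1]$; zero p-values
  from the vectorized ANOVA limit case are clamped to the smallest
  positive double before adjustment (thresholding is unaffected).
- All stage TSVs are written with fixed `%.10g` numeric formatting and
  fixed column orders; with a fixed seed, rerunning the pipeline
  reproduces the output tree byte for byte. No stage reads the clock
  or OS entropy.
- PSI-MITAB parsing interprets only columns 1, 2 (identifiers),
  5, 6 (aliases, preferring `(gene name)`-tagged entries) and 13
  (source database); symbols are uppercased. Graphs are keyed by gene
  symbol — not protein accession — because DEG tables and drug tables
  are symbol-keyed; `apply_id_map()` hooks in a user-supplied
  accession→symbol table, dropping and counting unmapped records.

# Limitations

- Interactomes are binary and unweighted; interaction confidence
  scores, directionality and taxonomy filtering are out of scope.
- The Fisher route's median-split table is one of several defensible
  dichotomizations; conclusions sensitive to it should use the
  pluggable table interface.
- The minimum-p platform merge is not a meta-analysis and slightly
  favors genes measured on more platforms.
- The consensus rule treats the five measures as exchangeable votes;
  they are correlated (degree and eigenvector especially), so "two of
  five" is a weaker requirement than it may appear.
- Multi-group designs beyond case/control are not implemented in the
  ANOVA route's vectorized path.
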