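---
title: "Multi-omics network diffusion: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics network diffusion: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modiplex)
```

# The problem

Single-omics networks — co-expression, protein co-abundance, co-methylation,
co-amplification and co-deletion graphs — each capture one regulatory level of
a disease system. modiplex integrates them without collapsing them: every
omics layer keeps its own edge set inside a *multiplex* network whose layers
share gene labels, drugs are attached through known drug–target associations,
and a random walk with restart (RWR) diffuses over the whole construction to
produce, for every gene and drug, a proximity profile over all other genes and
drugs. Downstream, that similarity space supports embedding, clustering,
over-representation analysis, nearest-neighbour search around a drug of
interest, and a trace-back of which omics layer carries any given association.

# Per-layer network inference

Quantitative layers (expression, proteome) are tested pair-by-pair with
Pearson or Spearman correlation. P-values use the t transform
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ — for Spearman this is the usual
large-sample approximation on rank correlations; at the cohort sizes this
tool targets (dozens to hundreds of samples) the approximation error is far
below the thresholds applied. P-values are Benjamini–Hochberg adjusted **per
layer**: each layer is an independently inferred network, so the layer is the
natural multiple-testing family. An edge requires both
$|\rho| \ge$ `min_abs_cor` (default 0.5) and adjusted $p <$ `max_fdr`
(default 0.05); the weight is $|\rho|$ and the sign is stored separately so
the diffusion engine only ever sees non-negative weights.

Binary event layers (methylation calls at `beta_threshold`, default 0.3, a
common methylation call cutoff; CNV split into separate amplification and
deletion matrices) are tested with Fisher's exact test on the 2×2 joint-status
table of every gene pair, Bonferroni-adjusted by the number of *actually
tested* pairs — genes with constant status are excluded before counting, which
keeps the family honest. Pairs passing the family-wise screen enter a post-hoc
stage: each of the four cells is compared to its independence expectation with
a per-cell chi-square goodness-of-fit test
($\chi^2 = (o - np)^2 / (np(1-p))$, df = 1), Bonferroni-adjusted across the
four cells. The edge is kept only when the joint-presence cell is a
significant **excess** — the procedure looks for co-occurrence, not mutual
exclusivity, so significant joint-presence *deficits* are discarded. The edge
weight is the joint-presence-cell statistic. The exact post-hoc contrast is a
declared design choice of this package: per-cell goodness-of-fit against
independence expectations is the simplest reading of "which cell drives the
association", and it is pinned by tests against an independent
`chisq.test`-based re-implementation.

The in-package `fisher_exact_2x2()` enumerates the hypergeometric support
directly. This is deliberate: the all-pairs scan evaluates thousands of
tables, and a vectorised enumeration over margins is much faster than calling
a general-purpose routine per pair. `stats::fisher.test` serves as the
independent oracle in the test suite, never as the implementation.

# Multiplex assembly

The unified gene set is the union over layers; genes missing from a layer are
inserted as isolated projections so that every gene exists in every layer.
Inter-layer coupling edges carry unit weight under two strategies:

* **node coupling** (default): each projection links only to its own gene's
  projections in other layers — exactly $|Genes| \cdot L(L-1)/2$ edges;
* **neighborhood coupling**: additionally links each projection to the other
  layers' projections of its first-order intra-layer neighbours.

Node coupling is the default because its edge count is exactly auditable and
it makes no additional assumption about cross-layer neighbourhood transfer.
The case-study-style multiplex is unweighted (`weighted_intra = FALSE` resets
intra-layer weights to 1); weighted diffusion remains available as an option.

Drug nodes attach through a bipartite drug–target table. Each (drug, gene)
association is replicated to the gene's projection in all $L$ layers with
unit weight. Drugs whose targets all fall outside the multiplex are removed
rather than kept isolated — an isolated drug would trap restart mass during
diffusion and contribute a degenerate similarity column.

# The diffusion model

The walker iterates
$$\bar p_{t+1} = (1-r)\,H\,\bar p_t + r\,\bar p_{RS},$$
where $H$ is column-stochastic and $\bar p_{RS}$ is the restart profile: a
gene seed restarts over its $L$ projections with layer weights $\tau$
(uniform $1/L$ by default; non-uniform $\tau$ prioritises a layer), a drug
seed restarts at its own node.

$H$'s column for a gene projection distributes mass as follows: if the gene
has drug associations, $\lambda$ goes to its drugs (uniformly); the remainder
splits $(1-\delta)$ over intra-layer neighbours (uniform, or
weight-proportional when weighted) and $\delta$ over inter-layer coupling
partners (uniform). Two conventions deserve note, both fixed here as package
design decisions and enforced by tests:

* $\lambda$ is applied **only** at nodes that actually possess bipartite
  links; otherwise $\lambda$-mass would leak into nothing at the vast
  majority of genes that no drug targets.
* When a projection has no intra-layer neighbours, its intra share is
  reassigned to the inter-layer share (and vice versa); when it has neither,
  the remainder self-loops. Drug columns send $\lambda$ uniformly over all
  target projections (targets × layers) and keep $1-\lambda$ as a self-loop,
  since the model has no drug–drug edges — this keeps $\lambda$'s meaning as
  the gene–drug transition probability symmetric on both sides.

Defaults: $r = 0.7$, $\delta = 0.5$, $\lambda = 0.5$, $\tau$ uniform,
L1 tolerance $10^{-10}$, `max_iter` 1000. The walk is a contraction for
$r > 0$, so the power iteration converges geometrically; non-convergence at
`max_iter` is flagged and logged, never fatal. The test suite pins the
iteration against the direct linear solve $(I - (1-r)H)\,p = r\,\bar p_{RS}$
on fixtures of up to 200 nodes, to an L1 discrepancy below $10^{-8}$.

At the stationary state each gene owns $L$ proximity values (one per
projection). They are collapsed by the geometric mean (default; arithmetic
mean and sum are available), and the collapsed vector is renormalised to a
probability vector — the rescaling convention keeps columns comparable across
seeds. The geometric mean of a profile containing a zero is zero, with no
epsilon: annihilation keeps the similarity matrix sparse and means "this node
is unreachable in at least one layer". One RWR per node, assembled
column-wise, yields the similarity matrix; the computation is deterministic
and embarrassingly parallel over seeds, though the implementation runs them
sequentially for simplicity at the scales it targets.

Layer contribution trace-back is the inverse read-out: the $L$ projection
values of a target gene in a seed's stationary vector, renormalised, say
which omics layer carries the association.

# Embedding, clustering, enrichment

The default embedding is a deterministic truncated SVD of
$\log(1 + S/\bar s)$, where $\bar s$ is the mean positive similarity — the
log transform tames the heavy tail of diffusion scores (the seed's own entry
dominates each column), and factor signs are fixed by forcing the
largest-absolute loading positive. External stochastic graph-embedding
methods can de-noise further at cohort scale, but a deterministic default
makes every downstream result exactly reproducible, which this package
values more at its validation scale; `method = "passthrough"` skips the step
entirely, as the embedding is beneficial but not mandatory. The default
factor count is 128 (bounded by the node count on small problems); the
validation runs below use 32 factors for a 162-node similarity space, which
already captures the planted structure.

2-D coordinates come from PCA (sign-fixed, deterministic), a seeded exact
t-SNE (quadratic in node count — intended for the few-hundred-node spaces
this package produces), or UMAP when the optional uwot package is present.
Clustering offers k-means (seeded), average-linkage hierarchical clustering
and DBSCAN (noise label 0). Cluster annotation is a local hypergeometric
over-representation test against user-supplied GMT gene sets, BH-adjusted
across terms; drug nodes are excluded from enrichment universes but
participate in clustering and neighbourhoods. All distances throughout are
euclidean in factor space.

# Functional evaluation

The silhouette evaluation asks whether functional co-participation is
reflected in distances. For each annotated anchor, $a$ is the mean distance
to its co-participants (genes sharing ≥ 1 term; for drugs, the genes of the
drug's pathways) and $b$ the mean distance to the other annotated nodes;
the score is $(b-a)/\max(a,b) \in [-1, 1]$. This per-anchor *binary*
labelling (co-participants vs the rest) is a declared design choice; a
multi-class variant would require an arbitrary assignment of genes to a
single primary term. Unannotated nodes are excluded both as anchors and as
comparison points so that embedding distances and PPI shortest-path distances
(breadth-first hop counts; infinite distances excluded from means rather than
capped with an arbitrary constant) are always evaluated on the same node
universe. Label permutation drives the mean score to zero — the metric is
honest under random labels, which the suite verifies.

# The synthetic generator

`synthetic_scenario()` plants modules that co-vary in **every** modality,
which is what the diffusion step is designed to exploit:

* quantitative layers: module genes load on a shared latent factor,
  $x = \sqrt{\rho}\,f + \sqrt{1-\rho}\,\varepsilon$, so the expected pairwise
  correlation is exactly the `cor_target` — the construction makes the
  generator itself testable (observed mean within-module correlation must
  land within ±0.05 of the target at 200 samples);
* methylation: a hidden per-sample module event switches all module genes
  between Beta(8,2) (methylated) and Beta(2,8) (unmethylated) draws;
* CNV: the same event model emits +1 calls for odd modules (co-amplification)
  and −1 for even modules (co-deletion); background genes fire independent
  sparse events.

The default scenario is 150 genes, 3 modules of 20, 200 samples per layer,
12 drugs of which 8 are module-aligned (all targets inside one module),
correlation target 0.8, event probability 0.4 against a 0.1 background, seed
17. These sizes keep a full pipeline run (five inferred layers → 762-node MH
network → 762 restart walks → embedding → clustering) under a few seconds
while leaving enough samples for the statistical stages to operate at their
nominal thresholds. What the generator does **not** emulate: batch effects,
sample-size imbalance between layers, tumor subtype structure, missingness
patterns, or the heavy-tailed degree distributions of real interactomes.
Passing the planted-module recovery checks therefore demonstrates the
pipeline's internal correctness and sensitivity under clean signal, not its
performance on cohort data.

Module recovery is scored on the planted-module genes with k = number of
modules: background genes are independent by construction, hence isolated in
every inferred layer, and their diffusion profiles are mutually equidistant
self-concentrated columns — they carry no clusterable signal, so "recovering
the planted partition" is evaluated where a partition was planted.

# Numerical and degenerate-input conventions

* Correlation of a zero-variance gene is undefined: such genes are excluded
  from testing and reported, never silently dropped.
* $|\rho| = 1$ maps to $p = 0$ rather than relying on the t transform at a
  pole.
* Fisher enumeration uses the customary $(1 + 10^{-7})$ relative tolerance
  when comparing outcome probabilities to the observed table's, protecting
  two-sided tie sums from floating-point noise.
* Ties in nearest-neighbour queries break by lexicographic node ID; k-means
  uses 10 seeded restarts; every stochastic step takes an explicit seed.
* A methylation gene with no observed value cannot be imputed and is dropped
  with a logged reason code; every dropped gene or drug is reported so that
  network sizes remain auditable end-to-end.
* Gene IDs are matched exactly (case-sensitive) across layers; no alias
  resolution is attempted, since silent identifier coercion is a classic
  source of phantom multi-omics overlap.

# Validation design

The suite validates each stage against an independent route: all-pairs
brute-force re-implementations of both inference cascades (via `cor.test`,
`fisher.test`, `chisq.test`) on random 60-gene matrices; exhaustive
enumeration pins for the hypergeometric quantities; the direct linear solve
for the diffusion; hand-enumerated transition columns on a 3-node network;
and a Monte-Carlo type-I check (an independent gene pair over 200 samples
produces essentially no false co-occurrence edges across 100 seeded
replicates). Cohort-scale bookkeeping is checked symbolically cheap but
exactly: a 5-layer multiplex over 19,929 shared genes must contain exactly
199,290 coupling edges, and a 4-layer multiplex over 19,592 genes exactly
117,552. End-to-end, the default scenario must yield planted-module ARI
≥ 0.8, positive mean gene silhouette, module-aligned drugs closer to their
own module, a permutation-null mean silhouette within 2 SE of zero — and a
multiplex whose inter-layer coupling has been shuffled must score worse,
confirming that the cross-layer structure (not any single layer alone) drives
the result.

# Known limitations

* All-pairs testing is quadratic in gene count; at 20k genes the correlation
  scan is feasible but the Fisher scan benefits from pre-filtering
  low-frequency events (as the thresholds encourage).
* The similarity matrix is dense $(|Genes|+|drugs|)^2$; cohort-scale runs
  should aggregate with `sum` or `arithmetic` if geometric annihilation
  removes too much signal under sparse layers.
* The exact t-SNE is quadratic per iteration and intended for plotting a few
  hundred nodes, not whole cohorts.
* Silhouette comparisons across annotation databases are only meaningful on
  the shared annotated universe; the report records skipped anchors and
  reasons for exactly this purpose.
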