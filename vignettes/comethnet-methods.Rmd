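---
title: "Co-methylation networks and site-level functional annotation: methods"
author: "comethnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-methylation networks and site-level functional annotation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comethnet)
```

# The problem

Single-base m6A maps (mi-CLIP, m6A-CLIP) tell us *where* RNA methylation
sites are, but not *what* they do. `comethnet` infers putative biological
functions for individual sites from the statistical structure of their
methylation levels across many MeRIP-Seq conditions: sites whose levels rise
and fall together ("co-methylation") are assumed to take part in related
regulation, the guilt-by-association principle that underlies co-expression
analysis. The deliverable per site is a set of GO biological-process terms
with enrichment p-values, plus an honest estimate of how much better the
network does than a degree-matched random graph.

# From read counts to a methylation matrix

The methylation level of site $i$ under condition $c$ is the pseudocounted
log2 fold enrichment of depth-normalised IP over Input reads counted in a
101-bp window centred on the site:

$$
m_{ic} = \log_2 \frac{\mathrm{IP}_{ic}/s_{\mathrm{IP}} + p}
                      {\mathrm{Input}_{ic}/s_{\mathrm{Input}} + p},
\qquad p = 0.5 .
$$

Size factors $s$ are classical median-of-ratios estimates
(`medianRatioSizeFactors()`), computed over sites with all-positive counts.
No dispersion shrinkage is performed: the network construction consumes any
reasonable per-site level, and the downstream statistics depend only on
ranks. The pseudocount (default 0.5, configurable) keeps levels finite for
empty windows and makes the zero/zero case exactly 0. Note one consequence
of ratio-based normalisation: a fold enrichment shared by *every* site is
absorbed into the size factors; quantification is anchored by the unenriched
majority of windows, as in real IP/Input data.

Biological replicates of a condition are averaged (`mergeReplicates()`),
missing cells ignored. GC-content bias is removed per condition by local
regression (`correctGCBias()`): a loess curve (span 0.75, degree 1) of level
on window GC fraction is subtracted and the condition mean restored, so
column means are preserved exactly. This is a deliberate, documented
detrending step, not a port of quantile-by-GC regression; it reproduces the
observable effect that matters here (conditions from the same cell line
cluster together once the GC trend is gone, visible with
`sampleDendrogram()`, Euclidean distance, average linkage). Outlier samples
are removed only through an explicit exclusion list — automatic outlier
hunting is easy to get wrong and is left to the analyst.

# Site filtering

Filtering runs in a fixed order (`filterSites()`), with strict inequalities
exactly as the thresholds are defined:

1. **Evidence mask** — a cell becomes `NA` when expression < 8 or IP+Input
   reads < 50 (`maskLowEvidence()`). The "expression value" is a per-site
   proxy: the mean normalised Input coverage of the site window; site-level
   Input coverage and gene-level expression are interchangeable for the
   purpose of flagging unquantifiable cells, and the proxy needs no
   annotation join.
2. **Missingness** — sites with more than 15 `NA` cells (of the 32
   conditions the pipeline targets) are dropped (`dropHighNA()`).
3. **Neighbour collapse** — same-chromosome pairs closer than 101 bp
   (|Δpos| ≤ 100) with pairwise-complete Spearman > 0.8 are treated as one
   site captured twice; the member with the lower mean level is dropped
   (`collapseNeighbors()`). Chains are resolved greedily in ascending
   genomic position, a deterministic rule verified in the tests against
   brute-force application on 3-site chains; the resulting set is re-scanned
   to prove no qualifying pair survives.
4. **Variability** — only sites with raw MAD of the level across conditions
   above 0.4 are kept (`madFilter()`). The MAD is computed *without* the
   1.4826 normal-consistency constant, on the reading that the published 0.4
   threshold is a raw MAD; the constant is exposed as an argument for users
   who disagree.
5. **Quantile normalisation** — columns are forced onto the mean-of-sorted
   reference; with missing data, per-column ranks are mapped onto the
   reference by linear interpolation on the common quantile grid, so missing
   cells stay missing. The operation is idempotent on complete data.

# The co-methylation network

All site pairs get a pairwise-complete Spearman correlation with average
ranks for ties (`spearmanMatrix()`); pairs with fewer than `minPairs = 10`
shared observations are undefined and can never become edges. Significance
uses the Fisher asymptotic approximation,

$$
z = \operatorname{atanh}\rho, \qquad
p = 2\,\Phi\!\left(-|z|\sqrt{n-3}\right),
$$

Bonferroni-adjusted over the number of *defined* pairs. An edge requires
both conditions: $\rho$ in the top or bottom 10% of all defined pair
correlations (boundary ties included — the quantile is a gate, not a fixed
edge count) *and* adjusted p < 0.05. Sites without an Entrez gene label are
removed before ranking; annotated isolated sites remain as nodes, because
hub detection and module membership are degree properties, not existence
properties. Edge signs record anti-correlation; MCL consumes $|\rho|$ as
weight so the flow matrix stays non-negative (`--weights unit` is available
for unweighted clustering).

`degreeFit()` fits the log-log degree-frequency slope by least squares over
positive degrees and requires at least three distinct degree values — on
degenerate graphs (regular graphs, stars) a power-law exponent is
meaningless and the function says so.

# The degree-preserving null

The random baseline rewires edges by repeated double edge swaps: edges
$(a,b),(c,d)$ become $(a,d),(c,b)$, rejecting proposals that create
self-loops or duplicate edges; rejections do not count as performed swaps
(`rewireNetwork()`). Every node keeps its exact degree. Two step-count
conventions are provided because the published description ("repeated 100
times") does not say whether steps scale with the graph: `"auto"`
(100 × |E|, the default — 100 total swaps barely perturbs a large graph) and
`"literal"` (100 swaps). Graphs that admit no valid swap (the triangle; any
degree sequence with a unique realisation, such as the 4-cycle plus chord)
are returned unchanged when the attempt budget runs out.

Two structural facts uncovered while validating the sampler are worth
recording. First, for some graphs the swap chain is *bipartite*: on the
labeled 5-cycle the 12 reachable cycles split into two parity classes and a
fixed number of successful swaps can only reach its own class; the test
suite therefore checks uniformity within each parity class, with the classes
enumerated exhaustively. Second, because only successful swaps count, the
chain is symmetric and its stationary distribution is uniform over each
reachable class, which is what the chi-square checks assert.

After rewiring, each real-network hub's neighbour-gene set in the random
network is subsampled to the hub's real neighbour-gene count
(`constrainNeighborGenes()`): hubs whose real neighbours collapse onto few
genes would otherwise gain spuriously many genes — and hence stronger
enrichment — under the null.

# Annotation

**Hub-based.** Hubs are sites with more than three neighbours
(degree ≥ 4). For each hub, the distinct host genes of its neighbours form
the study set; the hub's own gene is excluded (configurable) so a gene with
several clustered sites cannot confirm itself. Enrichment is one-sided
hypergeometric (`hypergeomEnrich()`) — the standard GO-enrichment test,
chosen because it is exactly testable by subset enumeration — against the
background of all genes hosting a network site (configurable). Enriched
terms (raw p < 0.05) are reduced to their minimal GO-slim ancestors
(`mapToSlim()`), each slim term inheriting the smallest p among its source
terms; GO:0008150 (biological_process) is excluded everywhere since every
reduction would otherwise contain it. The "known" terms of a hub are the
slim reduction of its own gene's propagated annotation — a deliberately
*soft* benchmark: a site's function need not equal its host gene's, and
nothing stronger is available at scale.

Performance is micro-averaged over hubs at a grid of cutoffs
(`pvGnSweep()`): PV bounds the enrichment p of a predicted slim term, GN
caps how many predicted terms are kept per hub (smallest p first,
deterministic term-id tie-break):

$$
\mathrm{Recall} = \frac{\sum_h |\mathrm{known}_h \cap \mathrm{pred}_h|}
                        {\sum_h |\mathrm{known}_h|},
\qquad
\mathrm{Precision} = \frac{\sum_h |\mathrm{known}_h \cap \mathrm{pred}_h|}
                           {\sum_h |\mathrm{pred}_h|}.
$$

Recall is non-decreasing in GN at fixed PV by construction (truncation can
only remove predictions), a property the tests fuzz.

**Module-based.** `mclCluster()` is a from-scratch dense Markov Cluster
implementation: add self loops (weight 1, the canonical choice), column-
normalise, then alternate expansion (matrix square), inflation (elementwise
power 1.4, renormalise) and pruning (entries < 1e-5 dropped, renormalise)
until the flow matrix changes by less than 1e-8 or 200 iterations pass.
Clusters are read from attractor rows; nodes supported by several attractors
go to the smallest-index attractor, an arbitrary but deterministic
tie-break. The pruning threshold and tolerance were fixed so that the
implementation is *identical* to a no-pruning dense oracle on all ≤ 30-node
test graphs. Clusters with ≥ 10 members are modules; each module's member
genes are tested for enrichment with BH adjustment *within* the module
(pooling across modules would let one strong module mask another; the
within-module choice is flagged as such). A module is significant when any
adjusted p < 0.05, and member sites inherit the module's enriched terms.

**Cross-method agreement.** For sites annotated by both methods,
`overlapTerms()` counts GO terms present in both the hub-based enriched set
and the module's enriched set (both at raw p < 0.05, pre-slim). Agreement on
the real network versus near-zero agreement on the rewired null is the
framework's internal consistency check.

# The synthetic study conditions

`simulateMethylation()` emulates the site-by-condition matrix with one
latent factor per planted module: site value = loading × factor(module,
condition) + N(0, noiseSd), background sites pure noise. Defaults — 300
sites, 32 conditions, 4 modules of 25 sites, loading 0.9, noise 0.3 — size
the generation to seconds while keeping within-module Spearman high enough
that edge recovery is a property of the method, not luck. Options plant a
linear GC trend and missing-at-random cells. Sites are spaced 1 kb apart
(the neighbour filter is inert unless duplicates are planted on purpose) and
each site gets its own host gene, so planted co-methylation modules are also
planted gene neighbourhoods.

`simulateOntology()` builds a three-level is_a DAG under GO:0008150: one
slim term per module plus 30 decoy slim terms, three leaf terms under each.
Module genes carry their module's leaves (probability = linkage; 1 in the
function-linked preset, 0 in the null preset) plus random decoy leaves. Two
generator choices matter and were made once:

* the slim vocabulary is large (34 slims) relative to the GN grid, as the
  ~150-term generic GO slim is in the real analysis — with a handful of slim
  terms a random predictor covers most of the vocabulary at GN = 16 and
  recall stops discriminating;
* each planted leaf has a unique minimal slim ancestor by construction, so
  slim mapping has known ground truth.

`simulateCounts()` inverts the quantification model (Input ~ Poisson(depth ×
expr), IP ~ Poisson(depth × expr × 2^level)), which makes parameter recovery
an end-to-end test of the quantification code. Because ratio normalisation
anchors on the unenriched majority, recovery fixtures plant non-zero levels
on a minority of sites.

The real-versus-random evaluation runs through the **full pipeline**,
filtering included. This matters: the MAD filter confines the network — and
with it the enrichment background — to the variably methylated sites. On the
raw synthetic matrix the annotated module sites are the only high-degree
nodes, so degree-preserving rewiring reconnects them mostly to each other
and the "random" network inherits the real network's functional coherence
through the background universe; that regime tells you nothing about the
method and does not arise in the filtered, sparse networks the method is
designed for.

What the generator does **not** emulate: read-level artefacts (fragment
distributions, antibody efficiency), correlated missingness, gene models
hosting several sites (every synthetic site has its own gene, so the
neighbour-gene constraint and same-gene exclusions are exercised only by
dedicated fixtures), scale-free degree structure (planted modules are
clique-like; power-law fitting is validated on preferential-attachment
graphs instead), and any biology in the decoy terms. Passing tests
demonstrate internal statistical correctness and the direction of the
real-versus-random contrast, not biological validity on real data.

# Problem sizes and numerical choices

The test-suite and acceptance-script study sizes are 300 × 32 matrices, 20
seeds for edge-recovery and real-versus-random comparisons (10 pipeline
seeds in the acceptance script), 10,000 permutations for the Monte-Carlo
check of the Fisher p-value, and 60-node planted-partition benchmarks for
MCL — sizes chosen so a full run completes in minutes on one core while
leaving the statistical margins wide (recovery ≈ 99% against an 80%
requirement; real recall ≈ 10× random). Degenerate inputs are contracts,
not surprises: |ρ| = 1 yields p = 0 with an underflow flag, empty
denominators in recall/precision yield 0 with a flag, regular graphs refuse
a power-law fit, and an edgeless network compares as 0-with-flag.

# Known limitations

* The soft benchmark rewards predicting the host gene's known annotation;
  genuinely novel site functions are invisible to recall/precision.
* Quantification is intentionally simple (no dispersion modelling, no
  shrinkage); levels for low-count sites are noisy, which the evidence mask
  mitigates but does not remove.
* The published node/hub counts include two mutually inconsistent figures
  (1899 vs 1889 hub sites; 13,363 nodes vs 13,415 − 52 annotated sites);
  the package retains all annotated sites as nodes and documents the
  discrepancy rather than resolving it.
* MCL here is dense (O(n²) memory); it is sized for networks of thousands
  of nodes, not millions.
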