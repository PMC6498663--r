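# comethnet

Functional annotation of individual m6A RNA methylation sites from an RNA
co-methylation network.

Base-resolution CLIP experiments locate m6A sites precisely, but say nothing
about what any particular site does. `comethnet` addresses this with
guilt-by-association: methylation levels (log2 IP/Input fold enrichments
from MeRIP-Seq) are quantified per site across many experimental conditions,
and sites whose profiles are strongly correlated — or anti-correlated — are
joined into a co-methylation network. Functions then flow along edges:

* **hub-based** — a site with more than three neighbours inherits the GO
  biological-process terms enriched among its neighbours' host genes,
  reduced to GO-slim terms;
* **module-based** — Markov clustering (MCL, inflation 1.4) finds network
  modules of 10+ sites, and each module's member genes are tested for GO
  enrichment (BH-adjusted), every member site inheriting the module's terms.

An edge joins site pair *(i, j)* when its Spearman correlation ranks in the
top or bottom 10% of all pairs **and** its Bonferroni-adjusted Fisher
asymptotic p-value, `p = 2Φ(−|atanh ρ|·√(n−3))`, is below 0.05. Predictions
are benchmarked against a degree-preserving edge-rewired null (double edge
swaps, with each hub's neighbour-gene count constrained to its real value),
with micro-averaged recall and precision

```
recall    = Σ_h |known_h ∩ predicted_h| / Σ_h |known_h|
precision = Σ_h |known_h ∩ predicted_h| / Σ_h |predicted_h|
```

swept over grids of PV (enrichment p cutoff) and GN (terms kept per hub).
The "known" terms of a site are those of its host gene — a deliberately soft
benchmark. Seeded generators build complete synthetic studies (planted
co-methylation modules, a toy GO-BP ontology with slim terms, IP/Input
counts), so everything is testable offline.

## Worked example

```r
library(comethnet)

st  <- syntheticPreset("function-linked", seed = 7)   # 300 sites x 32 conditions
res <- runPipeline(st$meth, st$sites, st$dag, st$annotation,
                   config = pipelineConfig(seed = 7))

res$network
#> CoMethNetwork: 98 sites, 476 co-methylation edges (n = 32 conditions)
#>   |scc| range 0.705..0.910; 476 positive, 0 negative edges
```

After filtering (the MAD filter keeps the 98 variably methylated sites), the
network almost perfectly recovers the four planted 25-site modules. The hub
sweep at GN = 16:

```r
res$performance[res$performance$gn_cutoff == 16,
                c("pv_cutoff", "recall", "precision")]
#>  pv_cutoff    recall precision
#>      0.100 0.5116279 0.8301887
#>      0.010 0.5116279 0.9777778
#>      0.001 0.4941860 1.0000000

res$baseline$performance[res$baseline$performance$gn_cutoff == 16,
                         c("pv_cutoff", "recall", "precision")]
#>  pv_cutoff      recall precision
#>      0.100 0.058139535 0.1923077
#>      0.010 0.023255814 0.3636364
#>      0.001 0.005813953 0.5000000
```

Real-network recall ≈ 0.51 and precision ≈ 0.83–1.0 versus ≈ 0.006–0.06 and
0.19–0.50 on the rewired null: the predictions come from network structure,
not from term frequencies. Recall does not reach 1 because each synthetic
gene also carries a random decoy term that neighbours cannot predict. The
module side agrees:

```r
sum(sapply(res$module_annotations, `[[`, "significant"))   # 4 of 4 modules
res$overlap$mean_overlap                                    # 4  (random: 0)
```

Per-site output tables (neighbour counts, known/predicted/hit term counts,
module terms) are written by `runPipeline(..., outDir = "results/")`, and
`inst/scripts/comethnet.R` wraps the same functions as a command-line tool
(`simulate`, `filter`, `network`, `cluster`, `run`).

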