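# miRcoNet

Integrative analysis of paired miRNA and mRNA expression profiles from
two-group designs, built for the question: *when a treatment (here, binge
ethanol drinking in mouse frontal cortex) shifts both miRNAs and mRNAs, do
the induced miRNAs preferentially target the induced or the repressed
genes?* The package is aimed at analysts working with paired expression
profiles plus target-prediction tables who want the whole chain — from
normalization to targeting networks and coexpression modules — reproducible
from one seed.

## What it computes

- **Moderated differential expression.** Per feature, the treated−control
  log2 difference with an empirical-Bayes moderated t: gene-wise variances
  are shrunk towards a scaled-F prior (d₀, s₀²) estimated by trigamma
  inversion, s²post = (d₀s₀² + d_g s²_g)/(d₀ + d_g),
  t = logFC / (s_post·√(1/n₁+1/n₂)) on d₀ + d_g df, BH FDR control.
- **Interaction universe.** miRNA→gene edges kept when predicted by ≥4 of
  11 tools or experimentally validated (validated takes precedence in
  deduplication), plus miRNA-family and cross-species homology mapping.
- **Targeting networks.** Bipartite networks over correlated DE sets
  (up-miRNAs × up-genes, up-miRNAs × down-genes), the average number of
  neighbors 2|E|/|V| over degree-positive nodes, randomized gene-set null
  networks, and per-miRNA/per-mRNA over-targeting via an upper-tail
  hypergeometric test P(X ≥ k) with population = expressed targetable
  genes; proportions compared by a df=1 Pearson goodness-of-fit test.
- **Cross-species overlap.** Monte Carlo significance of family/gene-set
  overlaps with the add-one estimator p = (1 + #{X ≥ obs})/(R + 1), and
  direction concordance of common genes.
- **Signed coexpression analysis** implemented from first principles:
  S = (1 + cor)/2, adjacency S^β (default β = 12, scale-free fit R²
  reported per power), topological overlap
  TOM_ij = (ℓ_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij), average-linkage module
  detection with static cut and eigengene-membership cleanup, SVD module
  eigengenes, kME/GS statistics, module–trait and module–miRNA correlation
  grids, hub subnetworks (MM > 0.5, GS > 0.5), and module-overlap tests
  between independently built networks.
- **Synthetic data.** `generateDataset(simConfig())` emulates the study
  conditions (20 + 12 samples, consumption ≈ N(4.92, 0.52) g/kg/3h vs 0,
  |logFC| ∈ [0.15, 0.7], trait-correlated modules, up-miRNA → up-gene edge
  enrichment) with per-stage seed substreams and full ground truth.

## Worked example

```r
library(miRcoNet)
report <- runPipeline(pipelineConfig(seed = 1), "demo_out", quiet = TRUE)
summarizeReport(report)
```

```
Seed 1 | miRcoNet 0.1.0
DE miRNAs: 43 up / 6 down; DE genes: 208 up / 217 down
Universe: 6629 edges (660 validated)
positive network: 43 miRNAs x 203 genes, 660 edges; mean degree 5.37 (null 2.92 +/- 0.16); overtargeting 39/43
negative network: 43 miRNAs x 128 genes, 189 edges; mean degree 2.21 (null 2.91 +/- 0.16); overtargeting 0/43
positive vs null proportion 0.00: chi2 = 18969.87, p = 0 (enriched)
negative vs null proportion 0.00: chi2 = 0.06, p = 0.803 (depleted)
Modules: 3 (+1310 grey genes)
  module blue       trait r =  -0.82  p = 1.19e-08
  module turquoise  trait r =   0.72  p = 4.08e-06
  module brown      trait r =  -0.02  p = 0.915
```

Read: in the simulated study the *positively correlated* network
(upregulated miRNAs targeting upregulated genes) is nearly twice as
interconnected as its randomized control (5.37 vs 2.92, a 15-SD excess) and
most upregulated miRNAs over-target upregulated genes (39/43), while the
*negatively correlated* network is indistinguishable from or sparser than
chance — the signature of an adaptive miRNA response to transcriptional
activation. The coexpression stage recovers trait-correlated modules
(|r| ≈ 0.7–0.8 with consumption) with unassigned genes in grey. Every
table behind these lines is written as TSV next to `report.json`, and the
run is byte-identical under the same seed.

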