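---
title: "miRcoNet: models, parameters and design choices"
author: "miRcoNet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miRcoNet: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRcoNet)
```

# Scope

miRcoNet implements an integrative analysis of paired miRNA and mRNA
expression profiles from a two-group design (here: ethanol-drinking versus
control mouse frontal cortex, 20 + 12 samples). The pipeline chains five
statistical stages: moderated differential expression, construction of a
consensus miRNA--mRNA interaction universe, bipartite targeting networks
with randomized null controls and over-targeting tests, cross-species
overlap tests, and a signed weighted coexpression analysis. A synthetic-data
generator emulates the statistical structure of such a study so every stage
is testable without microarray downloads.

# Differential expression

Expression is analyzed on the log2 scale. `quantileNormalize()` forces every
array onto the cross-sample rank-wise mean distribution (the package takes
log2 input as given; a bead-level variance-stabilizing transform is outside
its scope, and the downstream statistics depend only on a normalized
log-scale matrix). For single-color miRNA arrays, `scaleNormalize()`
equalizes per-array median absolute deviation and aligns medians, and
`collapseReplicates()` averages within-array replicate spots -- a
deliberate simplification of modelling a replicate-correlation nuisance
parameter, adequate because the replicate mean is an unbiased estimator of
the probe signal.

`fitModeratedT()` computes, per feature, the treated-minus-control mean
difference and an empirical-Bayes moderated t statistic. Gene-wise sample
variances $s_g^2$ (residual df $d_g$) are shrunk towards a scaled-F prior
with parameters $(d_0, s_0^2)$ estimated by moment matching on
$\log s_g^2$ (trigamma inversion; `estimateVariancePrior()`):

$$ s_{post}^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
   t = \frac{\overline{x}_T - \overline{x}_C}
            {s_{post}\sqrt{1/n_T + 1/n_C}} \sim t_{d_0+d_g}. $$

The limits behave as expected and are tested: $d_0 = 0$ reproduces the
classical pooled two-sample t exactly, and $d_0 = \infty$ fixes
$s^2_{post} = s_0^2$. P-values are two-sided; multiplicity is controlled by
Benjamini--Hochberg step-up (`bhAdjust()`), and `callDE()` uses a *strict*
threshold (`adj_p < fdr`), matching the convention "FDR < 10%" for miRNAs
and "FDR < 1%" for genes.

# Interaction universe

`buildUniverse()` composes the target universe from 11 per-tool prediction
tables and a validated-interaction table: a predicted edge is kept iff at
least 4 distinct tools support it, validated edges are always kept, and a
pair that is both yields one record with status `validated` and its tool
count preserved. Gene symbols are compared case-insensitively (human
symbols are upper-case, mouse title-case) with original casing preserved.

miRNA IDs are converted to species-neutral family IDs through a family map;
`familyFromName()` provides a name-based fallback (strip species prefix,
arm suffix, paralog letter). The two conventions genuinely disagree for
some miRNAs -- miR-93 belongs to precursor family mir-17, miR-152 to
mir-148 -- so cross-species family matching exposes both routes and the
tests document that only their union reproduces the published 14-family
human--mouse overlap. Gene symbols are translated across species through a
Homologene-style table (`mapHomologs()`), case-insensitively, with
unmapped symbols always reported rather than dropped.

# Targeting networks and over-targeting

`buildBipartite()` restricts the universe to a miRNA set and a gene set
(e.g. upregulated miRNAs x upregulated genes for the positively correlated
network). Only nodes with degree >= 1 are members; the summary statistic is
the average number of neighbors $2|E|/|V|$ over those members -- the
convention used by network viewers, and the one consistent with
back-calculating the published positive-network value (2E/(48+265) ~ 4.97).

Over-targeting of a miRNA is an upper-tail hypergeometric test. The
population is the set of *expressed, targetable* genes (expressed genes
with at least one universe edge): genes absent from the universe can never
be drawn as targets, and the published proportions (265/413 up, 119/296
down) count putative targets. Successes are the DE genes in that
population, draws the miRNA's expressed targets. The per-mRNA test swaps
the roles (population: expressed miRNAs in the universe; draws: miRNAs
targeting the gene), restricted to genes targeted by more than one miRNA.
One shared kernel (`hyperTailP()`, a `phyper` upper tail) serves
over-targeting, gene-set enrichment and module overlap, so identical counts
give bit-identical p-values; tests verify it against exhaustive subset
enumeration on every instance with N <= 12.

The randomization scheme is not specified by the study it follows, so the
package asserts one default: the miRNA set stays fixed and the gene set is
resampled uniformly without replacement from the expressed-and-targetable
genes, with the same cardinality as the DE set (`randomizeNetworks()`,
default R = 1000 replicates; the original analysis averaged two random
networks, and R is always recorded so either regime can be reproduced).
Degree-preserving edge swaps are a documented alternative, not the default.
Proportions of over-targeting miRNAs are compared to the null proportion by
a one-sample Pearson goodness-of-fit test (df = 1, no continuity
correction, two-sided): this is the unique variant that reproduces the
published P = 0.0016 from the split 10/41 against 0.49.

# Cross-species overlap

`montecarloOverlapP()` draws, in each of R replicates, a random subset of
the universe with the size of list A and counts its overlap with a fixed
list B; the empirical p-value uses the add-one estimator
$(1 + \#\{X \ge obs\})/(R + 1)$, which can never reach zero -- a published
"$P < 10^{-5}$ after 10,000 simulations" is reproducible only as the
estimator floor $1/(R+1)$ at larger R, and the package reports R explicitly
instead of reconciling that. The default overlap universe is the set of
families present on both platforms and is user-suppliable, since the
original universe is unstated. List A is randomized and list B fixed by
default (a symmetric option exists). `directionConcordance()` classifies
common genes by sign agreement.

# Signed coexpression analysis

All steps are implemented from first principles. Signed similarity
$S_{ij} = (1 + \mathrm{cor}(x_i, x_j))/2$; adjacency $a_{ij} = S_{ij}^\beta$
with default $\beta = 12$; `pickSoftThreshold()` reports, per candidate
power, the scale-free fit $R^2$ of log10(frequency) on log10(mean
connectivity) over 10 equal-width connectivity bins, choosing the smallest
power reaching the target (default 0.85) or else the argmax. Topological
overlap is
$\mathrm{TOM}_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$
with $\ell_{ij} = \sum_{u \ne i,j} a_{iu}a_{uj}$, verified against a
triple-loop oracle; TOM is computed unsigned on the signed adjacency (the
TOM variant is not pinned by the source analysis and is configurable in
principle).

Module detection is the static-height variant of dynamic tree cut: average
linkage on $1 - \mathrm{TOM}$, cut at `cutHeight` x the maximum merge
height (0.99 is interpreted on this normalized scale, consistent with
calling it "low" relative to a 0.995 default), clusters below
`minModuleSize` to grey, labels in the size-ordered color convention with
ties broken by first gene index. The deepSplit branch-splitting heuristics
are *not* reimplemented; in their place `detectModules()` offers the
eigengene-membership cleanup that block-wise module detection also applies:
genes whose correlation with their module eigengene falls below `minKME`
are reassigned to grey. The default `minKME = 0.45` is about 2.5 null
standard deviations of a correlation at 32 samples ($1/\sqrt{31} \approx
0.18$), so an unrelated gene is retained with probability ~1% while genuine
members (kME >= 0.6 for even the weakest planted loadings) are untouched.
Without this cleanup, loosely attached genes join large branches through
shared hub neighborhoods in TOM space -- the reason dynamic tree cut exists.
Block-wise processing is unnecessary at this scale and is replaced by a
single block.

Module eigengenes are first right singular vectors of the per-gene z-scored
module submatrix, unit norm, sign-anchored to correlate non-negatively with
the module's average standardized profile (the sign convention of the
original analysis is unverifiable; anchoring makes reruns deterministic).
Gene significance is stored signed and reported absolute; module membership
is the gene-eigengene correlation. Correlation p-values use the Student
transform $t = r\sqrt{n-2}/\sqrt{1-r^2}$; the module-eigengene x miRNA grid
is BH-corrected with flag FDR < 0.10. Hub subnetworks take genes with
MM > 0.5 and |GS| > 0.5 (strict), weight edges by adjacency and rank genes
by within-subnetwork connectivity. `moduleOverlap()` cross-tabulates two
decompositions and tests each cell hypergeometrically.

# The synthetic-data generator

`simConfig()`/`generateDataset()` produce paired expression, traits,
universe and ground truth. Defaults are the study conditions: 20 treated and
12 control samples; consumption ~ N(4.92, 0.52) g/kg/3h in treated animals
and 0 in controls; planted |log2 fold changes| uniform on [0.15, 0.7]; five
modules of sizes 180/140/120/110/110 with trait correlations 0.63, 0.55,
-0.63, -0.74 (echoing the strong module-trait rows) and 0 (pure
coexpression); residual noise sd 0.1 log2 units -- chosen once so that the
smallest planted fold change remains detectable at FDR < 10% in a 20 vs 12
design, the qualitative regime of the study; 2000 genes and 150 miRNAs
(desk-scale stand-ins for the array content); 30% of miRNAs DE, 90% of
those upregulated (upregulation dominated the study's miRNA changes);
baseline edge probability 0.02 with an up-miRNA -> up-gene odds multiplier
of 4 and 10% of edges validated.

One deliberate structural choice: because control consumption is zero, the
trait is nearly collinear with the group indicator, so any module latent
correlated with consumption necessarily carries a group-mean shift.
Planting DE shifts independently of modules would both mislabel module
genes (their group shift would be real but their truth label null) and let
scattered same-sign DE genes co-cluster into a spurious module. The
generator therefore delivers gene-level DE *through* the module loadings: a
DE gene in a module with trait correlation $\rho$ receives loading
$f / (|\rho| \cdot \Delta z)$, where $f$ is its drawn fold change and
$\Delta z$ the group gap of the standardized trait, making its expected
group difference exactly $f$ and keeping truth labels consistent with the
generative model. DE targets beyond the capacity of the trait-correlated
modules fall back to scattered group-shift genes (these share the treatment
covariate; the default configuration does not use them). Module latents use
exact in-sample mixing (the orthogonalized residual is standardized before
mixing), so the latent-trait correlation equals its target exactly rather
than in expectation. Each generation stage draws from a named substream of
the master seed, so adding a stage never shifts existing draws.

What the generator does *not* emulate: probe-level replicate structure,
intensity-dependent variance, batch effects, correlated noise between
miRNAs and their targets, and realistic universe topology (edges are
independent Bernoulli draws). Passing tests therefore demonstrate that the
statistics are implemented correctly under the assumed model, not that the
model captures every property of bead-array data.

# Problem sizes and numerical choices

The default synthetic dataset is 2000 genes x 32 samples with 150 miRNAs;
the module-recovery check runs on it directly, randomized-network
calibration uses 600-gene/60-miRNA replicates over 20 seeds with 200 null
networks each, and Monte Carlo overlap checks use 10^4 replicates -- sizes
chosen so the entire analysis is comfortable on a single desk CPU. For this
2000-gene simulation the pipeline default `minModuleSize` is 50 rather
than the 100 used on ~8000-gene array content; 100 would sit exactly on the
planted module sizes. Degenerate cases are defined, not left to chance:
zero-variance genes are dropped with a warning before correlation; an
all-equal connectivity vector reports scale-free fit 0; |r| = 1 returns
p = 0 from the Student transform; a singular module submatrix yields its
single distinct profile as eigengene; BH inputs outside [0, 1] and
hypergeometric overlaps exceeding min(K, n) are errors, never clamped.

# Known limitations

Module detection approximates deepSplit-style branch splitting with a
single static cut plus membership cleanup; strongly inter-correlated
modules (inevitable when several modules correlate with one dominant
trait) can merge into one label, which the module-overlap and eigengene
statistics make visible but do not undo. The variance-stabilizing
transform of bead-level data, annotation services, and figure layout are
out of scope. The cross-species fixtures ship only the family lists printed
in the source tables; the full human and rat DE tables are not
redistributed.
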