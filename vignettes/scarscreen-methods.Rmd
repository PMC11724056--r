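---
title: "scarscreen: models, synthetic data, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scarscreen: models, synthetic data, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Skin wound scarring is driven by fibroblast subpopulations whose
activation depends on the inflammatory infiltrate. An
inflammation-deficient mouse (a *PU.1*-null animal, lacking neutrophils,
macrophages, mast cells and T cells) heals wounds without inflammation,
so genes expressed lower in its wounds than in wild-type wounds are
*inflammation-dependent*. The screen this package implements crosses
that bulk contrast with three further, independent lines of evidence:

1. the gene must be a marker of some **fibroblast subcluster** in
   single-cell data of wound tissue (the cell population that actually
   builds scar matrix);
2. it must be **fibroblast-specific** rather than shared with
   macrophages or other infiltrating types;
3. it must be **upregulated in wound regions** of spatial
   transcriptomics sections relative to intact skin;
4. survivors are **ranked against a collagen anchor** (*Col1a1*): the
   genes whose subcluster profile tracks the most collagen-rich,
   late-phase fibroblast subclusters (F4, then F1) are the best
   scarring candidates — the *Itgbl1* pattern.

Every stage is an explicit, testable function; `run_pipeline()` chains
them and enforces the monotone nesting
`final ⊆ fibro_specific ⊆ union_hits ⊆ candidates`.

## The synthetic study and its ground truth

`synth_config()` defines the study conditions; the generators are the
package's test bed, not a fixture: they are tested code with planted,
recorded truth.

* **Populations.** Eight major cell types (fibroblasts F, macrophages
  M, neutrophils N, epithelial EpC, endothelial EC, pericytes P,
  mesenchymal MC, T cells TC) with eight fibroblast (F1–F8) and six
  macrophage (M1–M6) subclusters, across Days 3/7/14 post wounding.
  Composition shifts from inflammatory (N, M) toward fibroblast-rich
  over time; F4, F6 and F8 are absent on Day 3 and appear later, F5 is
  the resident intact-dermis fibroblast. Defaults: 1,000 genes, 3,000
  cells per timepoint, 25×25 spots at 100 µm spacing with a 700 µm
  wound disk and 20–30 cells per spot, 4 bulk replicates per genotype
  at depth 10^6 — desk-scale stand-ins for the tens of thousands of
  cells and ~700 spots of a real study.

* **Counts.** Gene-wise negative binomial draws with mean =
  depth × population transcript fraction. Single cells and spots use
  dispersion 0.2 (typical single-cell overdispersion); bulk replicates
  use 0.05, the realistic value for littermate replicates of an inbred
  strain — bulk libraries average millions of cells and are far less
  overdispersed than single cells. This split matters: at n = 4 per
  genotype a dispersion of 0.2 would make the candidate stage itself a
  coin flip for true fold-changes of −2, and no screen downstream of it
  could be exact. A spot's counts are drawn as NB with the summed
  per-cell mean and dispersion α/c (the exact second-moment match for a
  sum of c independent NB cells).

* **Planted truth.** Exclusive markers per major type and per
  subcluster (log2FC 2 by default); five true scarring genes
  (`Itgbl1` peaking in F4+F1 like the `Col1a1` anchor, plus `Clec3b`,
  `Ccl11`, `Lrrc17`, `Pi16` with other wound-subcluster patterns), all
  KO-downregulated and fibroblast-restricted; and one decoy per screen
  criterion: `Fbn1` (everything but the KO effect), `Col3a1`
  (pan-fibroblast, hence no subcluster marker), `Ccl8`/`Spp1`
  (macrophage genes), `Ccl7`/`C3` (fibroblast–macrophage shared, fail
  the specificity filter), and `Dpt` (expressed by intact-dermis F5
  fibroblasts, hence no wound-region support). A background of 60
  anonymous KO-downregulated genes gives the candidate stage a
  realistic size. A `Tgfb1` (macrophage) → `Tgfbr1` (F8) axis is
  planted for the communication stage, with ligand mass on the wound
  margin annulus and receptor mass at the wound center.

* **What the generator does not emulate.** No batch effects, ambient
  RNA, doublets, UMI chemistry, spot morphology or histology images, no
  muscle/scab regions, and no shared cells across timepoints. Passing
  tests therefore demonstrate correctness of the statistical machinery
  on clean, single-batch data — not robustness to the artifacts of real
  libraries, which would require the integration and QC machinery the
  package deliberately leaves out.

## Module-level methods and the choices behind them

### Single-cell stage

Normalization is log1p of counts-per-10,000. All fold-changes,
specificity scores and communication means are computed on
back-transformed (`expm1`, i.e. CPM-scale) cluster means, so they
estimate ratios of expression rates rather than ratios of log-values.

Clustering standardizes genes, projects to 30 PCs, builds a Euclidean
15-nearest-neighbour graph, and runs seeded Louvain modularity
optimization; labels are renamed by size. On data with genuine
subcluster structure Louvain resolves the terminal populations, which is
the desired behaviour: major types are obtained by annotating each
cluster with canonical markers (Dcn, Lyz2, S100a9, Krt10, Pecam1, Rgs5,
Bmp4, Cd3g) via mean z-scores and merging clusters with the same
annotation — the same overcluster-then-annotate pattern used in
practice. Fibroblast subclusters come from re-clustering the annotated
fibroblasts. The `resolution` parameter (default 1) mainly matters for
unstructured data: modularity optimization splits pure noise, so tests
of "one blob stays one cluster" use a coarse resolution (0.1).

Markers use a one-vs-rest Wilcoxon rank-sum: exact enumeration over
group assignments when the total sample is ≤ 30 cells (this is what the
4-vs-4 enumeration oracle checks: p = 2/70), otherwise the normal
approximation with tie correction, vectorized by ranking each gene once.
BH correction is applied within each cluster's family; a marker needs
q < 0.05, CPM-scale log2FC ≥ 0.585 (1.5×) and detection in ≥ 25% of the
cluster.

Fibroblast specificity of a gene is the fibroblast cluster's CPM mean
divided by the sum of all major-cluster means — 1 for an exclusively
fibroblast gene, 1/K for a flat one; the screen's threshold is 0.7.
Computing it on CPM-scale rather than log-scale means is essential:
log-scale means compress the ratio toward the threshold and make the
score depend on sequencing depth.

### Bulk stage

Size factors are median-of-ratios against the geometric-mean reference.
Dispersion is estimated per gene from *within-genotype* moments (pooling
across genotypes would inflate the dispersion of genuinely DE genes by
the between-group mean gap), with the small-sample bias of the plug-in
mean corrected by the `m² − s²/n` denominator, then shrunk with weight
0.8 toward a lowess trend fit with `iter = 0` — the robust lowess
iterations would track the median of the skewed per-gene estimates and
bias the trend low. The heavy trend weight is deliberate: at n = 4 the
per-gene moment estimate is so noisy that a lighter shrinkage makes the
Wald z anticonservative (empirically ~7% of null genes at p < 0.05
instead of 5%); with weight 0.8 the test holds its size (within
[0.035, 0.065] in a 2,000-gene null simulation) while keeping per-gene
signal for dispersion outliers. The Wald statistic uses the normal
reference; genes with base mean < 1 are flagged untested rather than
assigned p = 1 so the BH family stays meaningful.

One known property worth stating: with strongly *asymmetric* DE
(everything down in one genotype), median-of-ratios normalization
absorbs part of the effect and attenuates all fold-changes — a property
of the normalization, not the test. Calibration fixtures therefore
plant symmetric effects; the pipeline's own KO contrast (7% of genes
down 4×) is attenuated by well under 0.15 log2 units.

### Spatial stage

The reference is the per-type mean raw count vector normalized to the
simplex — raw counts, not log space, because the mixture model is
linear in transcript fractions. Deconvolution maximizes the multinomial
mixture likelihood by EM (uniform start, stop at max |Δw| < 1e−6 or 500
iterations), run simultaneously for all spots as matrix products. This
is a deliberate simplification of full reference-based decomposition
models: no platform effect, no per-gene overdispersion, no
doublet/singlet classification — a 20–30-cell spot is genuinely a
mixture of all types, and the transparent multinomial core is what the
grid-search oracle can verify. Before fitting, the gene set is reduced
to the union of the 50 most type-discriminative genes per type, which
concentrates signal the way established decomposition methods do. Two
numerical notes: the EM likelihood is nondecreasing by construction
(asserted on traces), and at a *boundary* optimum (a pure spot) the
multiplicative update converges sublinearly — off-support weights decay
like 1/iterations, so a pure spot reports ~0.998 rather than 1 ± 1e−6
at the default iteration cap. The estimated weights are transcript
fractions; they equal cell fractions when per-cell depth is
type-independent, as in the generator's defaults.

Region DEGs compare wound against intact spots per gene with the same
rank-sum machinery on log-CPM spot values, BH within each timepoint;
"spatially supported" means q < 0.05 with positive wound log2FC.

### Communication and direction

The cluster-to-cluster score reduces mass-action models with cofactors
to a single Hill term, score = x/(K_h + x) with x the product of sender
ligand and receiver receptor CPM means and K_h = 0.5. The reduction
preserves ranking (the Hill map is strictly increasing) which is how
such scores are used downstream; pathway aggregation is the probability
union 1 − Π(1 − score). Significance is by label permutation with the
add-one estimator, so p ≥ 1/(n_perm + 1) and the p-values are
super-uniform under exchangeability.

Direction fields solve entropic-regularized *balanced* optimal
transport from ligand mass to receptor mass with Euclidean cost in
micrometers, ε = 0.05 × median within-cutoff cost (relative, so the
field is invariant to grid rescaling), via log-domain-stabilized
Sinkhorn iterations. Pairs beyond the 500 µm cutoff are not excluded
outright but assigned a 4×-cutoff penalized cost: a hard exclusion can
make the balanced problem infeasible (a cluster of senders whose
admissible receivers cannot absorb their mass), in which case the
marginals provably cannot be matched; the soft gate keeps the problem
feasible while routing only the vanishing excess mass through long
edges, and the marginals then match to 1e−10. Spots with zero ligand
and zero receptor signal are excluded from the marginals. The sending
vector at a spot is its transport-weighted mean displacement,
unit-normalized, with the transported mass as magnitude; rotating the
coordinates rotates the field exactly.

### The screen

The four filters run in sequence with an explicit evidence trail
(per-gene subcluster membership and per-timepoint spatial support). Two
policies are worth making explicit. First, genes are kept when they
mark ≥ 1 fibroblast subcluster; membership is recorded so a stricter
≥ 2 rule can be applied downstream. Second, the anchor gene is held out
of the candidate set: the anchor is the screen's reference hypothesis,
correlates 1.0 with itself by construction, and a chance bulk
fluctuation should not let it outrank every candidate. Ranking uses
Pearson correlation between each survivor's mean-expression profile
across fibroblast subclusters and the anchor's profile; constant
profiles are flagged and ranked last, ties break lexicographically.

## Determinism and problem sizes

Every stochastic stage takes a seed derived from the configuration
seed, and RNG state is restored afterward, so the pipeline is a pure
function of (inputs, config): identical seeds give byte-identical
reports (asserted in the suite). The test suite and the acceptance
script run the full default study (9,000 cells, 3 × 625 spots, 8 bulk
samples), a 400-spot/6-type deconvolution fixture at ~5,000 counts per
spot, a 2,000-gene null calibration, and a 5-seed end-to-end screen;
the whole suite completes in a few minutes on one CPU.

## Known limitations

* The clustering stage assumes single-batch data; there is no anchor
  integration, and real multi-batch studies would need one upstream.
* The deconvolution model has no platform-effect term, so systematic
  single-cell-to-spatial capture differences would bias weights.
* Balanced OT forces all ligand mass to be transported; strongly
  unbalanced source/sink configurations are represented only through
  the soft distance gate.
* Permutation p-values have resolution 1/(n_perm + 1); pathway-level
  aggregation treats pairs as independent.
* The screen's exactness guarantee is a property of the planted study
  conditions; on real data the stages are filters with the usual
  type-I/II trade-offs, governed by the documented thresholds.
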