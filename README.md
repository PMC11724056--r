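# scarscreen

An integrated multiomics pipeline for identifying **inflammation-related
scarring genes** in skin wound healing, with a fully synthetic,
ground-truthed test bed.

Wound scarring is driven by fibroblast subpopulations that are activated
by the inflammatory infiltrate. Comparing wounds of wild-type mice with
wounds of inflammation-deficient (*PU.1*-null) mice isolates the genes
whose expression depends on inflammation; intersecting those genes with
single-cell fibroblast subcluster markers, a fibroblast-specificity
filter, and spatial (Visium-style) wound-region support yields a short
ranked list of candidate scarring genes — the *Itgbl1*-like genes that
peak in the late, collagen-rich fibroblast subclusters. `scarscreen`
implements each stage of that screen as a tested, reusable R function,
and ships a synthetic-data module that generates all three modalities
(single-cell, bulk, spatial) with planted ground truth so every stage is
falsifiable without downloading anything.

The package is aimed at computational biologists who want a transparent,
oracle-testable implementation of the workflow: spot deconvolution is a
multinomial mixture MLE solved by EM, communication scoring is a Hill
saturation on cluster-mean expression with permutation nulls, and
signaling direction fields come from entropic-regularized optimal
transport of ligand mass onto receptor mass.

## The core models

**Spot deconvolution.** Each Visium-style spot pools ~20–30 cells. With
a reference matrix *R* (cell type × gene transcript fractions, rows on
the simplex) built from annotated single cells, spot counts *y* are
modeled as a multinomial mixture and the weight vector *w* maximizes

&nbsp;&nbsp;ℓ(w) = Σ_g y_g log(Σ_k w_k R_kg),  w on the simplex,

via EM: z_gk ∝ w_k R_kg, then w_k ← Σ_g y_g z_gk / Σ_g y_g. The EM
log-likelihood is nondecreasing and, for small K, the solution matches
an exhaustive simplex grid search.

**Bulk differential expression.** Per gene, an NB GLM with genotype
indicator is fit by IRLS at a fixed dispersion (per-genotype moment
estimates shrunk toward a lowess mean–dispersion trend), and KO − WT is
tested with a Wald z. Candidates are genes with q < 0.05 and
log2FC ≤ −1 (down in the inflammation-deficient genotype).

**Communication and direction.** For sender i, receiver j and
ligand–receptor pair (L, R), x = mean(L|i)·mean(R|j) on the CPM scale
and score = x/(K_h + x); significance comes from label permutations.
Spatial direction per pair is the entropic optimal-transport plan from
ligand mass to receptor mass under Euclidean cost with a distance gate;
each spot's sending vector is its transport-weighted mean displacement.

**The screen.** candidates → ∩ fibroblast-subcluster markers →
fibroblast-specific (cluster-mean share ≥ 0.7) → wound-upregulated in
space → ranked by Pearson correlation with the *Col1a1* anchor profile
across fibroblast subclusters. Monotone nesting of the stages is
enforced, and every reported gene carries its evidence trail.

## Worked example

```r
library(scarscreen)

cfg <- pipeline_config(synth_config(seed = 7L),
                       run_deconv = FALSE, run_comm = FALSE)
pl <- run_pipeline(cfg)
print(pl$report)
```

```
screen_report
  stage counts: candidates=71, union_hits=8, fibro_specific=6, spatial_supported=5, final=5
  final ranked genes:
    1. Itgbl1   r=0.832  subclusters: F1,F4
    2. Ccl11    r=0.179  subclusters: F1,F3
    3. Clec3b   r=0.073  subclusters: F1,F3,F6
    4. Lrrc17   r=-0.108  subclusters: F2,F7,F8
    5. Pi16     r=-0.179  subclusters: F3,F6
```

Reading the output: 71 genes were significantly downregulated in the
inflammation-deficient bulk wounds; 8 of them are markers of some
fibroblast subcluster; 6 are fibroblast-specific (the two
macrophage-shared chemokine-type genes drop out); 5 are upregulated in
wound regions of the spatial data (the intact-dermis fibroblast gene
drops out). The final five are exactly the generator's planted true
scarring genes, and *Itgbl1* — whose profile peaks in subclusters F4 and
F1 like the collagen anchor — ranks first with anchor correlation 0.83.
The subcluster annotations are the detected (size-ranked) fibroblast
subcluster labels, so they need not match the planted names except by
membership pattern.

`run_pipeline()` also exposes every intermediate result: `pl$deconv`
(per-spot cell-type weights), `pl$comm` (ligand–receptor scores with
permutation p-values), `pl$field` (per-spot signaling direction
vectors), `pl$de`, `pl$markers_f`, `pl$region_degs`, and
`pl$proportions` (temporal subcluster composition).

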