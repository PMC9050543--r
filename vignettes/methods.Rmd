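---
title: "Models and methods of snmidbrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of snmidbrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snmidbrain)
```

# Scope

`snmidbrain` packages the analysis stages of a case-control single-nuclei
study of post-mortem midbrain — QC filtering, differential cell-type
composition, glial activation-trajectory analysis, immunofluorescence
morphometry, competitive genetic-risk enrichment, and cross-validated
annotation checking — together with synthetic-data generators that plant
known ground truth for each stage. Upstream steps (read quantification,
batch integration, graph clustering, UMAP, LD-aware SNP-to-gene analysis)
are deliberately out of scope: cluster labels, 2D embeddings and
gene-level association statistics are *inputs*, supplied either by the
user or by the generators.

# QC filtering

Barcodes are retained when **all** of the following hold, with the
inequalities implemented exactly as conventionally printed (strict for
the bounds, inclusive for detection):

* total UMIs > 1500 and detected genes > 1000 (strict),
* mitochondrial and ribosomal UMI fractions < 0.10 (strict), computed on
  the **raw** per-barcode totals — the fractions describe the barcode as
  sequenced, not a filtered version of it,
* doublet score < 0.15 (strict), skipped with a notice when no score
  column exists.

Genes are then dropped when detected in fewer than 3 barcodes (a gene in
exactly 3 is kept), and all mito/ribo-flagged genes are removed
regardless of detection. Stage order is barcodes → genes → doublets-as-
barcode-criterion, and every stage reports `retained + removed = input`
with per-criterion counts (overlaps allowed, so their sum may exceed the
union). Mito/ribo identity comes from generator flags or name-prefix
rules (defaults `MT-`, `RPS`/`RPL`); whether "ribosomal" means
ribosomal-protein genes or rRNA is not standardised, so the prefixes are
configurable and default to ribosomal-protein genes.

`score_doublets_simple()` is a self-contained stand-in for external
doublet callers (which are out of scope): simulated doublets are random
barcode-pair sums, and each barcode's score is the fraction of simulated
doublets among its k nearest neighbours in a 10-component PCA of
log-normalized expression. It separates planted doublets from singlets
on synthetic data but is not a validated caller for real tissue.

# Differential composition

**Embedding density.** Per-condition 2D Gaussian kernel densities are
computed on a shared 100×100 grid spanning the union range of both
conditions (5% padding), using the normal-reference bandwidth per axis;
grids are renormalized to integrate to 1. The contrast is
`log2((case + floor) / (control + floor))`; the floor defaults to one
count spread over the whole grid area, `1 / (n_cells × grid_area)`, and
cells where both densities sit below the floor are masked rather than
reported as 0. Densities are renormalized *before* the ratio (a flag
would be needed for raw per-bin counts; normalized ratios are the
default because the two conditions have different cell totals). Because
the normal-reference bandwidth scales with n^(−1/5), duplicating the data
changes the automatic bandwidth; an explicit `bandwidth` argument exists
for fixed-kernel comparisons.

**Proportion tests.** Per-sample cell-type proportions are compared with
the classical pooled-variance two-sided t-test (Welch by flag). When both
groups are constant a tiny variance guard (1e-12 of the data scale)
keeps the statistic defined: equal constant groups give t = 0, p = 1;
unequal constant groups give an effectively infinite t.

**Beta regression.** Each type's proportion is modelled as
Beta(μφ, (1−μ)φ) with logit μ = β₀ + β₁·condition + β₂·age + β₃·PMI and a
constant precision φ, fit by maximum likelihood (BFGS on the joint
(β, log φ) likelihood; no beta-regression package exists in the target
environment, so the fit is implemented here and verified by parameter
recovery, calibration and coverage tests). Standard errors come from the
observed information; non-convergence or a non-invertible information is
flagged on the fit, never silently replaced. Proportions touching the
boundary are first shrunk by the standard (y(n−1)+0.5)/n adjustment —
applied only when a boundary value is present, so interior data are
untouched.

**Pseudobulk and markers.** Pseudobulk profiles are per-type summed
counts scaled to counts-per-million and log2(x+1)-transformed; Pearson
correlations feed average-linkage clustering on 1−r (the linkage is a
documented choice; only "hierarchical clustering" is standard). Marker
scoring is one-vs-rest: AUC of normalized expression (counts per 10k),
logFC = log(mean_in+1) − log(mean_out+1) in natural log with pseudocount
1 (so the conventional 0.25 threshold is interpretable), detection
percentages, and a tie-corrected normal-approximation Wilcoxon p,
BH-adjusted within each type. The marker filter applies FDR < 0.05,
pct_in > 0.5, logFC > 0.25, all strict.

# Trajectory analysis

**Principal graph.** Elastic-graph methods (DDRTree-style) are replaced
by a documented surrogate: k-means centroids joined by a Euclidean
minimum spanning tree, with each cell projected to the nearest point on
the nearest edge. The downstream operations (rooting, pseudotime,
density contrast) depend only on *a tree plus projections*, and
topology-recovery tests (Y-shaped data must yield 3 leaves and one
degree-3 junction after degree-2 contraction) guard the surrogate's
adequacy. Duplicate centroids are jittered with a warning.

**Supervised rooting.** The root is the node maximizing the minimum
geodesic distance to the set of nodes nearest the known activated cells
— a maximin rule that treats multiple activated branch tips
symmetrically; ties break to the lowest node id. Pseudotime is the
geodesic distance from the root to each cell's projection,
min(d(root,u) + t·len, d(root,v) + (1−t)·len) for a projection at
fraction t along edge (u,v). On every test graph this equals an
independent Dijkstra oracle exactly (the unique tree path fixes the
summation order, so equality is exact, not approximate).

**Moran's I.** Weights are a k = 15 nearest-neighbour graph on the
embedding, row-standardized then symmetrized by averaging (the weight
graph underlying the published trajectory-gene tests is not specified;
kNN on the embedding is the default, with the statistic accepting any
weight matrix). I is computed in closed form with the expectation
−1/(n−1) and the randomization-assumption variance; the p-value is
one-sided (positive autocorrelation is what a trajectory gene produces),
BH-adjusted across genes. Constant genes are flagged undefined — never
reported as 0.

**Quasi-Poisson DE.** Per gene, a Poisson GLM of counts on condition
with a log size-factor offset (default: totals over their geometric
mean); the dispersion is the Pearson χ² estimate **floored at 1**, so
standard errors never shrink below Poisson — a conservative choice for
sparse counts. Wald tests with BH q-values; all-zero genes are excluded
and listed. An optional sample covariate absorbs within-condition batch
structure. The DE × trajectory intersection takes genes with q_DE < 0.05
and the requested coefficient sign, intersected with q_Moran < 0.05,
sorted deterministically.

# Morphometry

Bright-object segmentation is Gaussian smooth (σ per channel) →
binarize at ≥ threshold → drop components smaller than `min_object_px` →
optional hole filling → 8-connected labeling. Dark objects (neuromelanin
deposits on a bright field) binarize at ≤ threshold; running the bright
rule on the inverted image with the mirrored threshold gives the
identical mask. Thresholds support absolute and quantile modes and live
in configuration, never hard-coded. Myelin-like diffuse channels are
quantified as per-region positive-area fractions without segmentation.

Skeletons use **Guo–Hall** thinning. The classical Zhang–Suen scheme was
implemented first and rejected after it eroded a 104-pixel 45° strip to
3 pixels (an independent implementation preserves 29); Guo–Hall
preserves diagonal structure. Spurs shorter than 3 px (configurable) are
pruned before counting, because thinning artifacts otherwise inflate
branch counts.

**Branching statistic.** A branch point is a skeleton pixel whose
*crossing number* — the count of distinct 0→1 transitions around its
8-neighbour ring, i.e. the number of distinct skeletal branches leaving
it — is ≥ 3; an endpoint has crossing number 1. The naive "≥ 3 skeleton
neighbours" rule over-flags pixels diagonally adjacent to a junction even
on a perfect cross skeleton (5 pixels instead of 1), so it is reported
only as the alternate column `neighbor3_px`. The publication-grade
definition of "branching" is not standardised; this is the package's
documented choice, and the ground truth of the image simulator makes it
auditable: measured branch points are strictly monotone in the planted
process count.

Group comparisons are unpaired two-sided t-tests on per-individual means
(per region and whole-image), after averaging object-level metrics per
individual.

# Risk enrichment

Gene-level association p-values are inputs (the LD-aware SNP→gene step
requires reference-panel LD and is out of scope); z = Φ⁻¹(1−p). The
competitive test is OLS of z on set membership over the whole gene
universe with covariates (defaults: standardized log gene length and log
SNP count when provided), one-sided for enrichment, matching the
convention of competitive gene-set frameworks. exp(β) with its CI is
reported as a convenience odds-ratio-scale column, labeled as such —
whether published forest plots use exactly this transform or a logistic
refit is not stated, so the primary report is β itself. Case- and
control-stratified marker sets are independent analyses over the same
universe; the module never mixes strata.

# Annotation cross-validation

Normalization fits a loess curve of per-gene variance on per-gene mean of
log1p counts (span 0.5) and scales each gene by its fitted SD after
centering; zero-variance genes become all-zero and are flagged. Classes
are capped at the median class size (protecting rare classes from being
swamped and abundant ones from dominating), then split into **5 repeated
stratified 70/30 partitions** — the published "70% training / 30% test
5-fold" is internally tense (5 disjoint folds imply 80/20), so repeated
stratified splits are the default and a strict disjoint k-fold mode is
available by flag. Each training partition is reduced to 30 components
by truncated SVD (no centring, the sparse-friendly convention) and
classified; the default classifier is kNN with k capped at the smallest
training class (no tree-ensemble package exists in the target
environment, so the published random-forest ensemble is substituted by
kNN — the validation target, label recoverability via a confusion
matrix, is unchanged; a glmnet multinomial option exists). Classes
smaller than the fold count are reported untestable, never silently
dropped.

# The synthetic world

`simulate_counts()` emulates an 11-donor (5 control, 6 case), 12-type
midbrain cohort: oligodendrocyte-dominated composition with a case-side
gain of microglia/astrocytes and loss of oligodendrocytes; donor ages
~77–81 ± 5–6 years, post-mortem intervals ~16–22 h; a rare
case-exclusive neuronal cluster (0.6% of case cells, carved from a
neuronal parent type, placed at a distinct embedding location); flagged
mito (13 genes, low nuclear content) and ribosomal-protein (80 genes)
groups; per-type marker blocks (20 genes, 8-fold); per-sample log-scale
batch shifts (SD 0.15); library sizes uniform in [2000, 12000]; 5%
doublets formed as barcode-pair sums. Counts are gamma-weighted
multinomials — Dirichlet-multinomial overdispersion (the
negative-binomial analogue conditional on an exact library size), so
quasi-Poisson DE sees real overdispersion while singlet library sizes
stay exactly in range. Embeddings are drawn directly from a Gaussian
mixture per type rather than computed by dimensionality reduction:
manifold learning is out of scope and direct coordinates make density
tests exact. The desk-scale gene panel (1500) and cells per sample (400)
are configuration, not science; tests that need other scales say so.

`simulate_trajectory()` plants a Y-shaped latent tree (resting tip, two
activated tips) with cells uniform along root-to-tip paths; case cells
are displaced toward the tips by `condition_shift` (0 keeps the two
conditions identical in law). Trajectory genes follow monotone or
switch-shaped log-mean profiles (amplitude 1.5); condition-perturbed
genes (natural-log fold change 1) overlap the trajectory block first so
DE × trajectory intersections have known truth; counts are negative
binomial (dispersion 0.5).

`simulate_images()` renders per-marker canvases with pixel-aligned label
masks: microglia/astrocyte-like cells are capsule-shaped somata with
`branch_count` processes attached at distinct anchors. A purely radial
star was rejected: with 2 radial processes the skeleton thins to a
junction-free path (0 branch points, indistinguishable from 0
processes), whereas the capsule-with-perpendicular-processes shape makes
the measured junction count track the planted process count for every
k ≥ 1. Neuromelanin renders dark-on-bright; myelin as diffuse patches.
No optics PSF or ambient-RNA contamination is modelled; background is
Gaussian noise around a flat level — so a green morphometry test
establishes correct geometry and statistics, not robustness to real
microscopy artifacts. `simulate_iba1_cohort()` builds the two-group
morphology world: ramified controls (5–6 processes, small somata) vs
amoeboid cases (0–1 processes, larger somata, more cells).

`simulate_gene_stats()` draws z ~ N(γ₁·len + γ₂·snp + δ·enriched, 1)
with p the upper-tail probability, covariates correlated as in real
annotations, and overlapping set memberships.

All generators are pure functions of (config, seed); every planted truth
a downstream test needs is emitted machine-readably (metadata columns,
`truth` attributes, `truth.json` on disk).

# Numerical choices and degenerate inputs

* Strict vs inclusive QC inequalities follow the printed wording
  verbatim; all-zero barcodes get zero fractions plus a flag.
* The t-test variance guard is 1e-12 of the data scale; beta-regression
  starting values come from OLS on the empirical logit, φ starts at 10.
* p→z round trips are exact to 1e-10 on the upper tail; near p ≈ 1 the
  double representation of p caps accuracy at ~2e-8 in z (the float
  format, not the algorithm).
* Root ties break to the lowest node id; `top_contributors` breaks z
  ties lexicographically; intersections are sorted — all outputs are
  deterministic given a seed.
* Empty masks, empty regions, constant genes, single-label inputs and
  disconnected graphs raise flags or named errors rather than silently
  degenerating.

# Known limitations

* The principal graph is a k-means + MST surrogate, adequate for
  tree-shaped continua; it will not recover loops or high-dimensional
  structure.
* The doublet score is a neighbourhood heuristic, not a calibrated
  caller.
* TIFF support is the uncompressed single-strip grayscale baseline that
  the simulator writes — enough for the pipeline's own round trips, not
  a general microscopy reader.
* Beta regression uses a constant precision φ; no precision covariates.
* The annotation CV classifier is kNN/multinomial, not the published
  clustering-ensemble random forest; accuracy numbers are therefore not
  comparable between implementations, only the recoverability verdict.

Nothing in this vignette states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.
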