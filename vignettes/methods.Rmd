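---
title: "Meta-analytic cerebellar parcellation: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-analytic cerebellar parcellation: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cbparcel)
```

## The problem

Coordinate databases link thousands of task-fMRI studies to latent
functional topics and record each study's activation peaks in MNI
millimetre space. `cbparcel` turns such a database into a volumetric
functional parcellation of the cerebellum: which voxels respond together
across topics, and which topic families drive each territory. The package
treats all coordinates as world MNI mm throughout; voxelization happens
only inside the ALE and parcellation stages, on a configurable isotropic
grid (2 mm for production runs, 4 mm in most tests for speed — grid
spacing is a parameter, never hard-coded).

## Coordinate selection

The cerebellum is delimited geometrically: a bounding box
(−63 < x < 63, −103 < y < −28, z < 11 mm) plus two half-space planes that
trim the superior and posterior margins. Each plane is specified by two
anchor points and the slope/intercept are *derived* from them
(`plane_from_anchors`): the superior plane through (0, −50, 12) and
(±60, −50, −30) gives z < −0.70·|x| + 12; the posterior plane through
(0, −50, 12) and (0, −100, −15) gives z < 0.54·(y + 50) + 12. All
inequalities are strict, so the anchor points themselves are outside the
mask. Quality screening is declarative: studies carry flag strings
(e.g. `patients`, `resting-state`) and a study is dropped whole when any
flag is in the excluded set. An optional atlas labeler (any NIfTI label
volume plus a name list, `volume_labeler`) can additionally require a
cerebellar label per focus; the geometric mask alone is the default path.
Removals are attributed to the first failing criterion so the audit counts
always reconcile with the input. Activation direction is ignored
throughout: deactivations are treated like activations.

## Key-term centrality

Within a topic with ordered candidate terms and study sets
$S_1, S_2, \dots$, term $a$'s **uniqueness** is
$|S_1 \cup \dots \cup S_a| \,/\, |S_1 \cup \dots \cup S_{a-1}|$ and its
**overlap** is $|S_1 \cap S_a| \,/\, |S_1 \cup \dots \cup S_a|$. The
"number of studies for terms 1 to a" is read as the *cumulative union*:
uniqueness is defined as the relative increase of the study pool when a
term is added, which is only a meaningful increase under a union reading
(a conjunctive reading could never exceed 1). Terms are unique across
topics by construction (a shared term raises an error naming both topics).
A term is omitted when its overlap falls below `omission_fraction` (0.25)
times the grand-mean overlap; the grand mean pools all topics' term rows
2–5 and is computed before any omission. Whether the grand mean should
pool term rows or average per-topic means is genuinely open; pooled rows
is the default and a `pool = "topics"` switch exposes the alternative.
Reordering terms by centrality affects reporting only — a topic's selected
studies are the union over its kept terms' sets, which is order-invariant.

## ALE per topic

Each peak is modeled as an isotropic 3-D Gaussian with
$\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$, discretely normalized to unit
mass on the grid and truncated at 3×FWHM (then clipped at grid edges).
The default FWHM(n) follows the published two-component uncertainty model:
a fixed template term (5.7 mm Euclidean displacement) plus a
between-subject term (11.6 mm) attenuated by $\sqrt{n}$, displacements
converted to per-axis sigmas via $d/(2\sqrt{2/\pi})$. These coefficients
are a configuration default, not ground truth — a constant-FWHM kernel can
be supplied and the test suite uses explicit constant FWHMs so no result
depends on the coefficient choice. A study's modeled-activation (MA) value
at a voxel is the **max** over its foci, so reporting many nearby peaks
does not inflate a single study's evidence. Studies combine as
$\mathrm{ALE}(v) = 1 - \prod_i (1 - \mathrm{MA}_i(v))$.

The null distribution of ALE under independent random voxel assignment per
study is computed analytically: per-study histograms of masked MA values
are convolved through $u \leftarrow 1-(1-u)(1-m)$ on a fixed binning of
[0, 1). Numerical choices that matter:

* the distribution lives on **left-edge support values** $(k-1)/n_\text{bins}$,
  so the starting atom at ALE = 0 is represented exactly;
* transformed mass is **split linearly** between the two neighbouring
  support points, which keeps the distribution's mean exact at every step
  (a point-mass example stays a point mass up to one bin width);
* per-study histograms are compressed to at most `max_levels` (256)
  mass-and-mean-preserving support points before convolution;
* defaults: 10,000 bins; tests verify the null against a 10,000-draw
  permutation oracle on an 8³ grid.

The z-map is $z(v) = \Phi^{-1}(1 - p(v))$ with the right-tail p
interpolated within bins and clamped to $[10^{-12}, 1-10^{-12}]$ so z is
finite everywhere (ALE = 0 maps to the most negative finite z, about
−7.03). No thresholding or cluster forming is applied anywhere — the
pipeline deliberately keeps unthresholded z.

## Clustering and reconciliation

Each topic's z-map is unity-normalized over the mask
((z − min)/(max − min); a constant map normalizes to all zeros with a
warning), which equates topics with globally weak and strong activation.
The T × V matrix is clustered by agglomerative linkage on Euclidean row
distances. Complete linkage is the default (compact, relatively
independent clusters); Ward (`ward.D2`) is available. Merge-height ties
resolve by `stats::hclust`'s deterministic input-order rule, so runs are
reproducible for a fixed topic order. The cluster count k is chosen by the
user from the dendrogram; no automatic criterion is pretended.

When a parallel whole-brain solution exists, the two trees are reconciled
rather than concatenated (the per-database dendrograms are the primitive;
a feature-concatenation mode would hide which database drives a merge).
Cerebellar clusters get priority: a cerebellar cluster split across
whole-brain clusters is kept intact when its members join in the
whole-brain tree at ≤ `split_ratio_threshold` (default 0.5) of that tree's
maximum merge height, and split as the whole-brain tree dictates
otherwise. The threshold makes the qualitative "not too large a distance"
rule explicit and reportable; every kept/split decision is recorded.

## Winner-take-all parcellation

Cluster score maps aggregate member topics' normalized z by the **mean**
(max by flag). The matrix-decomposition phrasing of the underlying
procedure could also describe a factorization, but no factorization
algorithm is specified anywhere, so the operational rule — average, then
argmax — is implemented and the ambiguity is noted here. Each voxel takes
the argmax cluster; all-zero score vectors stay unassigned (label 0);
exact ties go to the lowest cluster index and are counted in the run
report (deterministic beats falsely random). Smoothing is a stochastic
mode filter: per sweep, masked voxels are visited in a seeded random
order and each label is replaced **in place** (sequential, Gauss–Seidel
style — matching the "random sweeps" phrasing better than synchronous
updates) by the modal label in a centred box; label 0 never enters the
mode count, so unassigned voxels are gradually absorbed by their labeled
neighbourhood. Defaults: 5-voxel box, 10 sweeps (3-voxel box for
whole-brain grids). Note the box is specified in voxels: on a 4 mm test
grid a 5-voxel box spans 20 mm, twice its 2 mm-grid extent, so smoothing
is relatively stronger in coarse test runs. On clean planted data at the
production 2 mm resolution the filter changes under 5 % of the voxels that
winner-take-all labeled; the larger total displacement figures one sees
include the label-0 periphery being absorbed, which is expected behavior
rather than boundary instability. Cluster → network merging is a pure
relabeling (the shipped map folds the three executive and two limbic
clusters, 10 clusters → 7 networks) and is idempotent.

## Validation

**Rand / adjusted Rand.** Computed from the contingency table on voxels
labeled in both parcellations; merge maps are applied first and labels not
covered by a map collapse into a single "other" category; per-network
comparisons binarize into network-vs-other. The adjusted index is the
Hubert–Arabie form. The implementation is tested against an exhaustive
all-pairs oracle on random partitions and against an independent library
implementation.

**DCBC.** Voxel pair distances are rounded to the nearest 2 mm and
assigned to bins centred at 6, 10, …, 50 mm; a rounded distance exactly
midway between centres goes to the lower centre (the rule is frozen by a
brute-force binner test). Per bin, the mean Pearson correlation of the two
voxels' topic profiles is computed separately for same-parcel and
different-parcel pairs — plain correlations, negative covariances not
truncated — and DCBC = within − between. Pairs within a bin are weighted
equally (bin weighting is not prescribed anywhere; equal weighting is the
simplest defensible choice and is stated here). Unpopulated bins are
reported as missing, not zero. Below `pair_budget` (2×10⁶) pairs are
enumerated exactly in chunks; above it they are subsampled with a seed.
Per-bin values are reported and the maximum flagged; no curve is fitted
through bins. Constant voxel profiles (zero variance) cannot enter a
correlation and their pairs are skipped.

**Split-half reliability.** Per repetition every topic's studies are
split into two non-overlapping halves (odd counts put the extra study in
half A after a seeded shuffle); each half gets fresh ALE z-maps and a
winner-take-all parcellation under the **fixed** topic→cluster model of
the full run; reliability is the between-half Rand, averaged over 20
repetitions, computed both on raw cluster labels and after network
merging (both variants are reported since either could be the quantity of
interest). Per-voxel displacement frequency is the fraction of
repetitions in which the halves disagree, and whitening masks flag voxels
above 30/40/50 % displacement. A paired-splitting mode plus a database
duplicator force the two halves identical, which must yield Rand exactly
1 and zero displacement — the degenerate anchor the implementation is
tested against.

## The synthetic generator

`generate_database` emulates the cleaned input the pipeline expects:
topics grouped into latent clusters; per-study peaks drawn as a region
centre (chosen by the topic's emission weights) plus isotropic Gaussian
scatter, with a `background_rate` fraction drawn uniformly over the
geometric mask; Poisson focus counts (mean 8, minimum 1) and Poisson
participant counts (mean 20, floored at 5 — a typical task-fMRI group
size); screening flags attached at configured rates. Isotropic Gaussian
scatter mirrors the ALE uncertainty model, so recovery of the planted
structure is well-posed; uniform background adds unstructured off-topic
peaks. A single seed fans out into per-(topic, study) substreams, so
enlarging the database never perturbs existing studies. The reference
scenario used across the recovery tests is 12 topics in 4 clusters
(3 topics per cluster — the smallest count that makes topic clustering
non-trivial), 40 studies per topic, 6 mm scatter, 10 % background.

What the generator does **not** emulate: topic-model fitting itself,
publication bias, spatially structured noise, inter-study heterogeneity of
effect location beyond Gaussian scatter, anisotropic smoothing, or
realistic cerebellar anatomy (regions are spheres; planted voxel labels
are the Voronoi partition of region centres restricted to the mask).
Passing recovery tests therefore demonstrates internal consistency of the
pipeline under its own assumptions, not performance on real data.

## Problem sizes and runtime choices

Tests and the acceptance script run on 4 mm grids (≈7,000 masked voxels)
with null histograms of 500–2,000 bins and 64–128 compression levels;
production defaults are 2 mm, 10,000 bins and 256 levels. Coarser null
bins only quantize a per-topic monotone transform of ALE, which the
subsequent unity normalization largely absorbs. The recovery experiment
runs 20 generator seeds; split-half runs its full 20 repetitions.

## Known limitations

* The analytic null assumes independent uniform voxel assignment per
  study — the same assumption the ALE literature makes — and is only as
  fine as its binning near extreme tails (p is floored at 10⁻¹²).
* DCBC inherits its documented bias toward smooth closed boundary shapes;
  interpret fragmented parcellations with care.
* The reconciliation threshold (0.5 of maximum merge height) is an
  explicit knob for a rule that is qualitative in the underlying
  procedure; sensitivity to it should be checked when the two trees
  disagree substantially.
* Real-database headline numbers require the original snapshot, manual
  screening decisions and external atlas volumes, none of which are
  bundled; the package validates the machinery on synthetic ground truth
  and ingests real data through the documented table and NIfTI dialects.
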