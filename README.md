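# cbparcel

Task-based functional parcellation of the cerebellum from coordinate
databases of neuroimaging studies.

Large text-mined coordinate databases (NeuroSynth-style) associate thousands
of fMRI studies with latent functional *topics* and report their activation
peaks in MNI millimetre space. `cbparcel` implements the full meta-analytic
parcellation workflow over such a database:

1. **Coordinate selection** — a geometric cerebellar mask (bounding box
   −63 < x < 63, −103 < y < −28, z < 11 mm, trimmed by two planes
   z < −0.70·|x| + 12 and z < 0.54·(y + 50) + 12, derived from anchor
   points), declarative quality-screening flags, and a pluggable atlas
   labeler.
2. **Key-term selection** — within-topic term centrality relative to the
   leading term: *uniqueness* |S₁∪…∪Sₐ| / |S₁∪…∪Sₐ₋₁| and *overlap*
   |S₁∩Sₐ| / |S₁∪…∪Sₐ| over study sets, at most five unique terms per
   topic, and omission of terms whose overlap falls below 25 % of the
   grand-mean overlap. The 22-topic key-term configuration ships with the
   package.
3. **ALE meta-analysis per topic** — each peak becomes an isotropic Gaussian
   (FWHM shrinking with sample size), per-study modeled-activation maps
   take the max over foci, studies combine as ALE(v) = 1 − ∏ᵢ(1 − MAᵢ(v)),
   and an analytic permutation null converts ALE to unthresholded z-maps.
4. **Topic clustering** — unity-normalized z-maps form a topics × voxels
   matrix; topics are clustered hierarchically (complete linkage on
   Euclidean distance, Ward optional), with a reconciliation rule that
   gives cerebellar clusters priority over a parallel whole-brain solution
   unless the whole-brain tree separates their members at large height.
5. **Winner-take-all parcellation** — per-cluster mean score maps, argmax
   labelling per voxel, stochastic 5-voxel box mode filtering over 10
   seeded random sweeps, and cluster → network merging (the shipped map
   folds 10 clusters into 7 networks).
6. **Validation** — distance-controlled boundary coefficient (DCBC:
   within-parcel minus between-parcel mean Pearson correlation of voxel
   topic profiles at matched distances, bins centred 6–50 mm), Rand and
   Hubert–Arabie adjusted Rand similarity with merging rules, split-half
   reliability (20 repetitions of per-topic half-splits with a fixed
   cluster model) with per-voxel displacement maps, and recovery scoring
   against planted ground truth.

A synthetic database generator with planted topic clusters and spherical
activation regions makes every stage testable end to end without any
external download.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the
reference synthetic scenario (12 topics in 4 planted clusters, 40 studies
per topic, 6 mm peak scatter, 10 % background foci) and write their tables
under `results/`:

```sh
Rscript analysis/01_simulate.R 1       # database + planted truth
Rscript analysis/02_mask_and_screen.R  # geometric mask + screening audit
Rscript analysis/03_term_centrality.R  # term uniqueness/overlap + omission
Rscript analysis/04_ale_maps.R         # per-topic ALE z-maps (NIfTI)
Rscript analysis/05_cluster.R          # dendrograms + reconciliation
Rscript analysis/06_parcellate.R 1     # winner-take-all + mode filter
Rscript analysis/07_validate.R 1       # DCBC, recovery, split-half
```

A run at seed 1 prints, among others:

```
simulated 480 studies (12 topics, 4 planted clusters), 3858 foci
studies: 480 in, 57 removed by screening, 0 emptied, 423 kept
complete vs ward at k=4: ARI 1.00
parcellation: 4 clusters over 6971 masked voxels; smoothing moved 39.0% of voxels (0 WTA ties)
DCBC peaks at 0.205 at 30 mm equidistance
recovery vs planted regions: Rand 0.846, adjusted Rand 0.640
split-half over 20 reps: mean Rand 0.747 (ARI 0.339)
```

Meaning: the topic clustering recovers the four planted clusters exactly
(complete and Ward linkage agree, ARI 1.0); the voxel parcellation matches
the planted Voronoi regions with Rand 0.85; parcel boundaries separate
functionally dissimilar tissue (positive DCBC in every populated bin); and
repeating the parcellation on random half-databases reproduces it with mean
Rand 0.75. The "smoothing moved" figure is dominated by unassigned
periphery voxels that the mode filter absorbs into neighbouring parcels.

The same functions accept any foci table in the documented CSV/TSV dialect
(`read_foci_table`) and any NIfTI label volume for cross-atlas comparison
(`read_volume`, `rand_report`, `per_network_rand`), so the workflow applies
unchanged to a real NeuroSynth-style snapshot.

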