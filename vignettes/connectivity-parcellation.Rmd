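---
title: "Connectivity-based parcellation and cross-species fingerprints: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based parcellation and cross-species fingerprints: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbparc)
```

# The model and its assumptions

Connectivity-based parcellation rests on one assumption: voxels belonging
to the same functional-anatomical subregion share a long-range connection
profile. The pipeline therefore treats each seed voxel as a point in
"connection space" — its row of streamline counts to all targets — and
clusters those points.

**Similarity.** The clustered object is the voxel × voxel matrix of Pearson
correlations between connectivity profiles. A raw product of the count
matrix with its transpose is scale-dependent (voxels near white matter emit
more reconstructed streamlines), so correlation of rows is used: it equals
the cross-product after row standardization and is invariant to positive
affine rescaling of any profile. Voxels with a constant profile (typically
zero streamlines everywhere) are retained with similarity 0 to all other
voxels rather than dropped, so the parcel geometry is preserved; they are
reported with a warning. Counts are not log-transformed before
correlation: the simplest reading, and one the min–max fingerprint
normalization downstream makes largely immaterial.

**Spectral clustering.** Several details are deliberately fixed because the
choice must be reproducible: negative correlations are clipped to zero to
obtain a valid affinity (a correlation of −0.3 between profiles is evidence
of *different* clusters, not of a weak connection between the voxels); the
embedding uses the symmetric normalized Laplacian (top-K eigenvectors of
`D^-1/2 A D^-1/2`, rows scaled to unit norm); and the embedding is
partitioned by k-means with 10 restarts under a caller-supplied seed, so
the whole path is deterministic given `rng_seed`. If the thresholded
affinity graph is disconnected the function warns and proceeds — the
leading eigenvectors are then component indicators and the embedding
separates components naturally; only when there are *more* components than
clusters does a fallback engage (the K largest components become cluster
cores; smaller ones merge into the core with maximal mean raw similarity).

**Label alignment.** Cluster indices from independent runs are arbitrary.
Before any cross-subject aggregation, each subject is aligned to a
reference (by default subject 1) by the label permutation maximizing total
voxel overlap, found by exhaustive search over the K! permutations — exact
and instant for the K ≤ 5 used here (a greedy assignment covers larger K).

**Group maps and the MPM.** The group probability map of cluster *c* at
voxel *v* is the fraction of subjects labelling *v* with *c*. The maximum
probability map assigns each voxel with any support to the argmax cluster.
Exact probability ties (common with small even cohorts: 6/12 vs 6/12) are
broken by the higher mean probability over the voxel's 26-neighbourhood
(the 3×3×3 cube minus the centre, clipped at grid borders — the only
neighbourhood with exactly 26 voxels); a residual exact tie falls back to
the lower cluster index with a warning. With a single subject the MPM
reproduces that subject's parcellation exactly.

**"Median" filtering of labels.** Median filtering of nominal labels is
ill-defined; the order-free reading is modal filtering: one pass in which
each in-mask voxel takes the most frequent label among its in-mask
26-neighbours, ties keeping the original label. It is exposed as a step
applicable to a subject parcellation or to the MPM; the intended default
place in the pipeline is the MPM, after group aggregation.

# Choosing the number of clusters

Four indexes compare two parcellations through their contingency table
over jointly labelled voxels (background excluded on either side, since
group maps need not share support): multi-label Dice (after alignment),
Cramér's V (`sqrt(chi² / (N·(min(r,c)−1)))`, empty rows/columns dropped;
degenerate single-margin tables score 0 with a warning), NMI
(`2I/(H(X)+H(Y))` — the symmetric, bounded convention; other
normalizations exist and change the scale), and variation of information
(`H(X)+H(Y)−2I`). Entropies use natural logarithms, so VI is in nats; the
choice of base only rescales VI and is fixed and documented rather than
configurable.

Reproducibility per candidate K is measured by split-half resampling: the
subjects are repeatedly split at random into two equal halves (sizes
differing by one for odd counts), an MPM is built per half, and the index
between the two MPMs is averaged over repetitions (the reference protocol
uses 1,000; tests here use 200, which leaves the Monte-Carlo error well
below the between-K differences at desk scale). The reference protocol
specifies this scheme for Cramér's V; Dice, NMI and VI are computed under
the same scheme for uniformity, since no alternative protocol is stated
for them — subject-vs-subject or subject-vs-MPM averaging are defensible
alternatives that would change the absolute values but not the ranking in
our experiments.

The optimal K is the one with the best total rank across the four indexes
(CV, Dice, NMI: higher is better; VI: lower), exact ties going to the
smaller K. A rank-based rule is used rather than any weighted combination
because the indexes live on incomparable scales.

# Connectivity fingerprints

A fingerprint is a region's vector of connection values over a fixed,
ordered target list (the package ships the 19 homologous target ROI names
as the default order). Structural values are streamline fractions: total
counts from the region to the target divided by (region size × streamlines
seeded per voxel) — scale-invariant under the normalization that follows,
so the exact denominator convention is immaterial to comparisons.
Min–max normalization maps the strongest target to 1 and the weakest to 0;
it is idempotent and rank-preserving, and a constant fingerprint is an
error rather than a silent zero. Functional values are Pearson
correlations between region time series; target selection uses a strict
threshold (`> r_min`) with descending ordering, matching the convention
"coefficients higher than the cutoff".

Cross-species matching computes the full cosine-similarity and
Manhattan-distance matrices over all region pairs. Cosine similarity is
the primary criterion (argmax per row); the Manhattan-distance best match
is reported alongside, and disagreement between the two criteria — or an
exact CS tie — is flagged, never silently resolved. Group-level
fingerprints average per-subject values elementwise for structural data
and on the Fisher-z scale for correlations, the variance-stabilizing
defaults.

# The synthetic cohort: what it emulates and what it does not

The generator stands in for per-subject tractography output. Its defaults
— 12 subjects, a 10×10×3 voxel seed grid, 2 planted clusters, 19 targets,
2,000 streamlines per voxel, separation 0.5, subject jitter 0.1, noise
floor 0.05 — define the reference desk-scale cohort used by the test
suite. The counts are multinomial with a fixed per-voxel total, which
preserves the sum constraint genuine streamline counts have; a real
acquisition seeds more streamlines per voxel (thousands to tens of
thousands), and 2,000 keeps the same counting statistics at a size where
the full pipeline runs in seconds. Cluster profiles mix a shared positive
base vector with disjoint-support cluster-specific vectors
(`theta_c = (1−separation)·base + separation·delta_c`), per-subject
variability is log-normal jitter on the profile followed by
renormalization, and a uniform noise floor emulates spurious streamlines.
Planted clusters are contiguous slabs along the grid's longest axis, so
spatial operations (modal filtering, the 26-neighbourhood tie-break) act
on realistic geometry.

What the generator does **not** emulate: spatial autocorrelation of noise
within a cluster, registration error across subjects, distance-dependent
streamline attrition, gyral bias, or partial-volume mixtures at cluster
borders. Passing tests therefore demonstrate that the pipeline's
machinery is correct and recovers planted structure under realistic
counting noise — not that any particular parcellation of real tissue is
right. Region time series come from a latent Gaussian factor model with a
prescribed correlation matrix (PSD verified through the
eigendecomposition, so exactly collinear targets are allowed); this is
sufficient because the functional analysis consumes only Pearson
correlations, and no haemodynamics are simulated.

With these defaults the planted two-cluster structure is easy — subject
and MPM recovery reach Dice 1 — which is intentional: the reproducibility
*trend* across K (indexes falling, VI rising as K exceeds the planted
number) is the scientifically meaningful readout, and it is averaged over
five cohort seeds in the tests to keep it a property of the generative
conditions rather than of one draw.

# Numerical and interface choices

- Voxel indexing is 0-based in world-coordinate conversions and R-native
  1-based in arrays; scan order is x fastest, then y, then z, matching R's
  linear indexing. World coordinates exist only through the affine.
- Cross-volume operations require identical grids (shape equal, affine
  within 1e-4 mm) and raise an error rather than resampling.
- Matrices are written as tab-separated UTF-8 with `.` decimal at 17
  significant digits, so write/read round trips are lossless to 1e-12;
  label volumes round-trip NIfTI exactly, with non-integer values beyond
  1e-6 of an integer rejected.
- Exact floating-point equality is the tie criterion in the MPM (group
  probabilities are small rationals, so genuine ties are exact);
  neighbourhood-mean comparisons use a 1e-12 band.
- All stochastic steps (cohort generation, k-means restarts, split-half
  resampling) take an explicit integer seed and are bit-reproducible.

# Known limitations

- The split-half protocol is one of several defensible ways to attach
  Dice/NMI/VI to a candidate K; published absolute values obtained under a
  different (unstated) protocol — notably VI magnitudes — are not
  comparable to ours, which are definitional nats.
- Spectral clustering details (Laplacian normalization, restarts, negative
  clipping) follow one standard, fixed recipe; other recipes can move
  borderline voxels.
- No registration, preprocessing, or tractography is performed; inputs are
  assumed co-registered on a common grid.
- Hemispheres are units of analysis: the seed mask passed in defines the
  scope, and pooling across hemispheres is left to the caller (per-region
  fingerprints can be pooled with `pool_fingerprints()`).
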