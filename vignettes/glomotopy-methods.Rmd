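---
title: "Quantifying retinotopy in an optic glomerulus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinotopy in an optic glomerulus: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glomotopy)
```

This vignette is the package's own account of its science: the statistic
at its core, the geometric and statistical conventions behind each
analysis, what the synthetic connectome generator emulates (and what it
does not), and the numerical choices a maintainer should know about. It
states no empirical result beyond what the test suite and
`scripts/acceptance.R` compute themselves.

## The Retinotopy Index

Retinotopy means neighbouring neurons encode neighbouring points in visual
space. To ask how much of it a mapping preserves, each point of an
N-point set is taken in turn as a reference; the other N−1 points are
ordered by distance to it in the source space and again in the target
space, and the two orderings are compared by counting inversions — the
minimal number of adjacent transpositions (bubble-sort swaps) S that turn
one into the other, equivalently the number of discordant pairs. With the
normalization A = (N−1)(N−2)/4, the mean inversion count of a uniformly
random permutation (half of the maximum (N−1)(N−2)/2, by the symmetry that
pairs every permutation x swaps away from the identity with one
(N−1)(N−2)/2 − x away), the per-reference index is RI_i = 1 − S/A and the
population RI is the mean over references. For tie-free rankings RI_i is
exactly Kendall's tau-a between the two distance-rank vectors; the suite
asserts this against `stats::cor(method = "kendall")`, and asserts the
merge-counting implementation against a literal bubble sort and A against
exhaustive enumeration over all permutations for N = 3…8.

Three conventions matter:

* **Ties.** With continuous coordinates exact distance ties are
  measure-zero, but constructed inputs (lattices, squares) produce them.
  Ties are broken by ascending neuron id, identically in both spaces, so
  an exact tie never contributes a spurious inversion; tied adjacent pairs
  are flagged in the `RankList`.
* **Significance.** The per-point values of one mapping share points and
  are statistically dependent, so the p-value attached to a population RI
  is approximate by construction. The default test is the two-sided
  Wilcoxon signed-rank test of the per-point values against zero;
  `riSignificance(method = "mannwhitney")` instead compares them to a
  user-supplied null sample (for example per-point RIs of randomized
  mappings). Both implement "compare the population to zero"; the
  signed-rank form was chosen as the default because it needs no null
  sample.
* **Metrics.** `pointMapping()` accepts coordinates under Euclidean or
  great-circle metrics, or a precomputed symmetric distance matrix, so the
  synapse-based distance of `presynapseDistance()` feeds the same core.
  RI is invariant under any similarity transform of either space, which
  the suite asserts directly.

RI has known limits: orderings react to arbitrarily small jitter, and a
1-D inversion count compresses 2-D/3-D arrangements, so absolute values
are less meaningful than comparisons against the package's null mappings
(`fullRandomize()`, `blockRandomize()`, rigid transforms) and idealized
projections.

## Null mappings and the idealized glomerulus projection

`blockRandomize()` tiles the bounding box of the point set (anchored at
the box minimum; partial edge blocks allowed) and permutes positions
within blocks only: with one block it is a full randomization, with
one-point blocks the identity, and expected RI rises monotonically as
blocks shrink. The idealized glomerulus projection `axisProjection()`
models the glomerulus as a 1-D line: eye points are placed on the unit
sphere (longitude ∈ [−90°, 90°], latitude ∈ [−10°, 160°] — one eye's
spherical-lune field of view, with latitudes beyond 90° wrapping over the
pole), rotated about the radial axis through the lobula midpoint
(longitude 73°, latitude 0°) by the projection angle using unit-vector
algebra (Rodrigues' formula; the scalar positions are compared with plain
absolute differences, the one natural metric of a line), and their new
azimuths are read off. Angle 0° returns the raw longitudes (the
anterior–posterior projection); angles are taken modulo 180° because a
line-space has no orientation; a point sitting exactly on a rotation pole
has no azimuth and is an error. `projectionSweep()` scores, per angle
(default 0°–170° in 10° steps), the RI from the eye sheet to the line and
from the line to observed 1-D glomerulus positions.

## Skeleton geometry

Skeletons are rooted trees of 3-D nodes in nanometres (standard 7-column
SWC; cycles and dangling parents are rejected with the offending node
ids). `resampleSkeleton()` places nodes at ≈400 nm arclength spacing along
each unbranched path, preserving the root, branch points, and leaves, so
node density becomes cable density and node means/medians are
arclength-weighted. Downstream conventions:

* **Cross-sections** (`crossSectionPositions()`): a neuron's position at a
  planar section is the mean of its nodes inside a 1 µm slab (closed
  interval ±t/2); positions are put in a canonical 2-D frame by the
  similarity transform sending a chosen reference pair to (0, 0) and
  (0, 1), which removes any rigid motion of the raw coordinates (asserted
  to 10⁻⁶). Neurons missing from the slab are omitted and reported.
* **Long axis** (`glomerulusLongAxis()`): the first principal component of
  the presynapse cloud — the canonical elongation axis of a point cloud,
  validated on synthetic cylinders to within 2° — with the centroid as
  origin. Clouds whose top two eigenvalues are within 5% are flagged
  near-isotropic (direction arbitrary).
* **Glomerulus mask** (`glomerulusMask()`): the volume demarcated by the
  presynapses, realized as their principal-axes bounding box dilated by a
  configurable margin (default 1 µm). A dilated box was chosen over an
  exact convex hull as the package's membership primitive; for restricting
  skeletons to the glomerulus the difference is a thin shell at the
  corners.
* **Axon tips** (`axonTipPosition()`): the mean of the 10% of nodes
  farthest from the glomerulus entry, with "farthest" measured
  geodesically along the arbor from the node nearest the entry landmark —
  robust to curled axons — and a Euclidean option behind a flag. The
  fraction is taken over glomerulus-restricted nodes (restrict and
  resample first).
* **Compartments** (`partitionCompartments()`): boundaries at the j/k
  quantiles of projected presynapse positions so each of the k = 10
  compartments holds ⌊n/k⌋ or ⌈n/k⌉ presynapses (presynaptic connectors
  only — synapses are polyadic, and the postsynaptic fan-out is ignored
  for the partition). Ties at a boundary go to the lower compartment in
  input order; a partition whose ties straddle a boundary is flagged
  degenerate but stays deterministic.

## Connectivity statistics

`lcLcDistanceBias()` asks whether neuron-to-neuron synapses prefer
partners with nearby eye coordinates. For each presynaptic neuron the
distances between dendrite centers (great-circle degrees on the lune by
default; a chordal/Euclidean fallback is exposed) to its N−1 partners are
weighted by the pair's synapse count (both directions pooled) and
averaged. The null permutes each neuron's partner-distance vector with the
counts held fixed — only identity labels are scrambled, positions stay
put, so the non-uniform density of dendrite centers is present in the null
as well; permuting the counts instead would be algebraically identical for
the weighted mean. The p-value is one-sided (bias = smaller distances)
with ties between null and observed counted half, so a weight-invariant
(uniform) connectivity sits at p = 0.5 rather than 1. Per shuffle, both
the multiset of distances and of weights are preserved exactly.

`presynapseDistance()` defines a neuron-pair distance from synapse
geometry: for every presynapse of A the nearest presynapse of B is found,
the same from B into A, and the pooled mean is returned — symmetric and
zero on identical clouds by construction, but not a metric (the triangle
inequality can fail, and is deliberately not asserted).
`compartmentRI()` feeds this distance, restricted to selected
compartments, into the RI machinery with eye centers as the source space;
its control permutes the assignment of presynapse clouds to neuron
identities first. `targetProximityProfile()` slices the glomerulus along
the long axis (default 80 × 1 µm; the slice range follows the projected
presynapse extent, so a "bulk" restriction is a caller-side choice of
axis extent), reduces each projection neuron to one position per slice
(the mean of its in-slice nodes), and averages over all
projection-node × target-node pairs per group; slices without target
nodes are reported missing, never zero. `synapseDensityPerCable()` clips
each skeleton edge to the slices for the cable denominator, assigns
synapses to their nearest node, and summarizes the maximum relative
deviation of density from its mean.

Nearest-neighbour searches are computed exactly (vectorized distance
matrices); at the point-set sizes of glomerulus analyses (≤ a few
thousand presynapses per neuron pair) this is faster in practice than
spatial indexing in R.

## Mapping dendrites to eye coordinates

`fitDendriteSurface()` fits a least-squares quadratic height field over
the PCA plane of all dendrite nodes (≥6 points; the frame is forced
right-handed so results are reproducible up to the documented `flip`
convention). `mapToEye()` then maps the surface onto the lune by geodesic
polar coordinates about the eye-center reference column: a query is
projected to the surface (queries farther than 3 rms residuals trigger a
warning with the distance); its on-surface arclength from the center
(integrated numerically along the straight frame-plane path, which for
radial geodesics of a near-spherical patch is the projected geodesic)
becomes the angular distance from the lune anchor (longitude 0,
latitude 75 — the lune midpoint); and its angular coordinate, zeroed at
the meridian reference, becomes the bearing, so the meridian column lands
on the central meridian by construction. The global scale is set so the
meridian reference lands at its known eye position (an argument, default
latitude 115). The exact surface-to-sphere parameterization is not
uniquely determined by two anchor columns; geodesic polar coordinates were
chosen because they are exact for spherical patches, and the suite
validates the choice by round-tripping a synthetic spherical-lune
embedding to under 1° and checking that mapped mesh triangles never flip
orientation. The two reference columns enter as coordinates — how they
were identified anatomically is outside the computation. Handedness is a
display convention (right-hemisphere data conventionally shown mirrored):
the mathematics is convention-free and `flip` mirrors the bearing.

`dendriteCenter()` is the arclength-weighted mean of dendrite-labeled
nodes; `coveragePolygon()` is the convex hull of mapped dendrite nodes,
and `luneCoverageFraction()` rasterizes polygon unions to check
full-field tiling.

## Receptive fields

`anatomicalRF()` places one 2-D Gaussian per neuron at its eye center,
height proportional to that neuron's synapse count onto the target of
interest, and sums. All Gaussians share a half-width, interpreted as the
half-width at half-maximum — σ = halfWidth/√(2 ln 2), with 30° as the
default (the scale of a dendritic arbor radius); the conversion constant
is a function argument, not a hidden constant. Distances are planar
lon/lat degrees by default because the fields are drawn on the flattened
lune; a great-circle variant is exposed for sensitivity analysis. Field
values are in arbitrary units — the proportionality constant cancels in
contours and argmax positions, which are the quantities interpreted.
Linearity (field of summed weights = sum of fields) makes
`populationRF()` a pointwise sum, mimicking a calcium indicator expressed
across a population; `compartmentRF()` reuses the machinery with
per-compartment presynapse counts as weights. `rfContour()` traces
fraction-of-peak level sets (70% anatomical, 60% functional by
convention) with bilinear-interpolated marching squares
(`grDevices::contourLines`); contours meeting the grid boundary are
returned open and flagged.

## Imaging summaries

ΔF/F = (F − F₀)/F₀ with F₀ the 10th percentile of fluorescence — a
robust baseline — inside a sliding 300-frame window, centered on each
frame and clipped at the trace edges (the alignment is a package choice;
an `epoch` mode uses one global percentile instead, for protocols where a
single baseline period is appropriate). Per-fly responses are normalized
by that fly's 98th percentile across all stimuli (a robust peak level),
removing per-animal gain; at least 50 values per fly are required for the
percentile to be meaningful. `functionalRF()` averages normalized peaks
per stimulus location, tests each location with a one-sided one-sample
t-test against zero (responses larger than zero) under Benjamini–Hochberg
FDR control at α = 0.05, interpolates the means bilinearly from the
stimulus grid onto a finer eye-coordinate grid, and attaches the 60%
contour. Per-fly means (one value per fly per location) are the test
units. `tuningComparison()` regresses log-normalized paired peak
responses and reports slope and Pearson r; `bilateralSuppressionTest()`
is a two-sided paired t-test of ipsilateral-alone versus
bilateral-presentation peaks with the effect direction reported.

## The synthetic connectome generator

The generator exists so every analysis above can be validated against
known ground truth. Its defaults are fixed, chosen once to emulate the
LC6 system, and the tests run at these defaults unless stated:

* **65 neurons** drawn from a 6 × 11 lattice spanning the lune, jittered
  with σ = 3°, with lattice longitudes warped by the inverse CDF of a
  linear density 1 − slope·|lon|/90 (slope 0.5) so dendrite centers are
  denser near the visual midline.
* **Glomerulus** modeled as a cylinder, 40 µm long × 5 µm radius — the
  analyses only need positions, so a simple elongated volume suffices.
* **Scramble** ∈ [0, 1] is the retinotopy dial, implemented as rank
  mixing: the axon's 1-D axis placement ranks are a convex combination of
  the latitude rank and a random permutation's rank, re-ranked. This
  interpolates cleanly between RI ≈ 1 and RI ≈ 0 and is monotone in
  expectation, which the acceptance suite checks at five scramble levels.
  Because scramble 0 means perfect retinotopy of axon *positions*, the
  axon's entry position in the cylinder cross-section also mirrors its eye
  coordinate at scramble 0 and blends to a random disc position at 1.
* **Axon length** is coupled to the (scramble-mixed) latitude rank with
  correlation `axisCoupling` (default 0.8), so longer axons reach the
  glomerulus tip and axis medians reflect eye latitude — at full scramble
  no latitude information survives anywhere.
* **Presynapses** (60 per neuron) are scattered uniformly along the
  distal 40% of the in-glomerulus axon — the spatial distribution of
  presynaptic sites along an axon is not otherwise constrained, and
  uniform-along-arclength is the neutral assumption — with ±300 nm
  transverse jitter.
* **Neuron–neuron synapses**: pair counts are Poisson with rate
  ∝ exp(−d/20°) in great-circle eye distance, scaled to ~1900 synapses in
  total (≈29 received per neuron), matching the reported census scale.
* **Targets**: per-target synapse counts are a single multinomial draw
  with weights ∝ Gaussian(rf center, spread) at each neuron's eye center,
  so they sum exactly to the configured total; a zero spread degenerates
  to the nearest neuron. The default two targets (900 and 430 synapses,
  one excitatory and one inhibitory, spread 30°) echo the synapse-count
  scale of strongly and moderately connected glomerulus target classes.
* **Seeding**: one global seed is expanded into named substreams (layout,
  census, scramble, coupling, entry, presynapses, neuron-neuron, targets),
  so adding a component never perturbs another and identical config + seed
  reproduces the connectome bit for bit.

What the generator does *not* emulate: axon tortuosity and fasciculation,
reconstruction/proofreading noise, per-neuron variation in arbor size,
the geometry of polyadic contacts, and any network dynamics. Passing
parameter-recovery tests therefore shows the *analyses* are correct and
sensitive under the stated statistical structure — not that real
glomeruli have that structure.

`makeTraces()` closes the loop for imaging: per stimulus location a flat
baseline plus a triangular transient with amplitude gain × field value at
the stimulus center (unit peak guaranteed at one frame, so noiseless
peak ΔF/F is exact), plus optional Gaussian noise. The suite round-trips
synthetic connectome → anatomical RF → traces → ΔF/F → peaks →
functional RF and requires the recovered 60% contour to match within two
grid steps.

## Numerical choices and problem sizes

Quantiles use R's type-1 (inverted ECDF) for compartment boundaries so
boundaries are data points; permutation p-values use the mid-p convention
for ties; slab and mask membership use closed intervals; all coordinates
are nm and all eye angles degrees with no implicit conversion. The test
suite sizes its simulations to run on one CPU in minutes: 100 seeds per
scramble level (five levels), 20 seeds for RF-center recovery, 100
paired runs for the compartment-RI-versus-control comparison, 1,000
random permutations for null calibration, and 1,000 all-noise replicates
for the FDR calibration; seed-sweep unit tests use a reduced generator
configuration (20 neurons, 20 presynapses each) where the full-size
defaults are exercised in the acceptance suite. Monte-Carlo assertions use
3-standard-error bands.

## Known limitations

The RI p-values ignore the dependence between per-point values; the
surface-to-lune map is one defensible parameterization among several (it
is isolated behind `mapToEye()` so alternatives can be swapped); the
presynapse distance is not a metric; and the generator's glomerulus is a
cylinder — adequate for positional analyses, silent on fine axon
morphology. Functional RF inputs are assumed already motion-corrected and
in eye coordinates; registration, ROI segmentation, and stimulus
rendering are out of scope.
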