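---
title: "Measuring the reproducibility of manual bundle segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the reproducibility of manual bundle segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bundlerepro)
```

## The measurement problem

Manual "virtual dissection" of a white-matter bundle selects a subset of
streamlines from a whole-brain tractogram using inclusion and exclusion
regions of interest. Two raters following the same written protocol on the
same tractogram rarely return the same subset, and the same rater rarely
returns the same subset twice. `bundlerepro` quantifies that variability in
two representations that answer different questions:

* **Streamline representation.** A bundle is a set of streamline indices
  into the shared parent tractogram. Agreement here is strict: a streamline
  either was or was not selected by both raters, no matter how close its
  neighbours are.
* **Voxel representation.** A bundle is the set of voxels its streamlines
  pass through. This view forgives index-level disagreement: two raters who
  pick different members of a dense, spatially coherent bundle still cover
  almost the same volume. Converting to voxels acts like a spatial
  smoothing of the selection.

The package's central empirical contrast — visible in every simulated
study — is that voxel-wise agreement is systematically higher than
streamline-wise agreement when the compared selections are drawn from the
same coherent bundle core.

## Data model and conventions

All streamline coordinates live in world millimetres, RAS orientation.
Every object carries a `ReferenceGrid` (shape plus 4×4 voxel-to-world
affine, the information in a NIfTI header). Voxel indices are 0-based with
centres at integer voxel coordinates; a world point belongs to the voxel
whose half-open cube `[i − 0.5, i + 0.5)` per axis contains it. TRK files
store points in voxel-scaled coordinates with the origin at the corner of
voxel (0,0,0); they are mapped to world mm through the header affine on
read. TCK files are world mm natively. Keeping one internal convention
avoids the classic half-voxel and corner/centre dialect bugs.

**Streamline identity is the index into the shared parent tractogram.**
Bundles returned as files are resolved to indices by hashing per-streamline
coordinates rounded to the matching tolerance (default 1e-3 mm, comfortably
above float32 storage error and far below inter-streamline distances); a
hash miss falls back to a direct same-point-count comparison. When the
parent contains geometrically identical streamlines, matches claim the
lowest unclaimed parent index, processed in a canonical key order so the
result cannot depend on file order. The matching rule is this package's
design choice: since all raters segment bit-identical parent tractograms,
coordinate identity is well-defined and resolution stays O(n).

## Voxelization

`densityMap()` counts, per voxel, the number of *distinct* selected
streamlines touching it — a streamline contributes at most once per voxel.
Two modes:

* `points` — a streamline touches exactly the voxels containing its sample
  points. This reproduces the didactic worked example exactly and is the
  right mode when points are dense relative to the voxel size.
* `segments` (default) — additionally walks every voxel the polyline
  crosses, via an incremental 3D grid traversal (Amanatides–Woo) in C++.
  Compressed or sparsely sampled streamlines can hop over voxels between
  consecutive points; segment traversal makes the support contiguous along
  each streamline. Every points-mode support voxel is by construction also
  a segments-mode support voxel.

Out-of-grid points are clipped with a warning rather than failing hard:
rigid study transforms can push edge voxels outside the grid, and losing a
handful of boundary points should not abort a study. The clip count is kept
on the object.

## Agreement measures

For selections `A`, `B` (index sets) or mask supports:
Dice `2|A∩B|/(|A|+|B|)`, Jaccard `|A∩B|/|A∪B|`, related by
`D = 2J/(1+J)`. Two empty inputs score 1 (perfect agreement on selecting
nothing — this keeps `m(a,a) = 1` an identity); empty versus non-empty
scores 0. Reports flag the convention.

Density-map correlation is the Pearson r of per-voxel counts over a chosen
support. The default support is the **union of the two maps' nonzero
voxels**: over the full grid the overwhelming number of shared zeros would
inflate r towards 1. Full-grid and user-mask supports remain selectable.
Zero variance on the support is an explicit error, never a silent `NaN`.

Confusion counts classify every element of a stated universe. Defaults:
all streamlines of the parent tractogram, or all voxels of the grid. A
segmented bundle is a tiny fraction of either universe, so true negatives
dominate; specificity and accuracy then saturate above 0.99 and Cohen's
kappa converges to Dice (with TP, FP, FN fixed and TN → ∞ the limit is
exact; at TN = 10⁶ the gap is below 1e-3). Because the TN/TP ratio differs
between representations, restricted universes (`"support"`, a user mask)
are available.

Per-bundle descriptive measures (`bundleStats()`): streamline count, volume
as support-voxel count × voxel volume in cm³, mean polyline arc length in
mm, and mean scalar (e.g. FA) over the support — unweighted by default,
density-weighted on request. Which voxelization feeds the volume is a
user-visible `mode` argument; the default is segment traversal.

## Vote-based consensus

`voteMap()` counts per-element rater votes; `thresholdVote(v, k)` keeps
elements with at least `k` votes. Threshold semantics are `≥ k`, so 1-of-N
is exactly the union, N-of-N exactly the intersection, and consensus
selections nest monotonically as `k` rises. Ratio thresholds convert by
`ceiling(r · n)`, making anything above 0.5 a majority vote: with 11
raters, `r = 0.51` and `k = 6` coincide. `buildGoldStandard()` builds the
streamline-universe and voxel-universe consensus **independently** — the
voxel gold is voted from the per-rater masks, not derived from the
streamline gold — because the two universes genuinely differ (disjoint
streamline picks can still share voxels). All outputs label the result an
*average segmentation*: it approximates what the rater group agrees on, not
true anatomy.

## The blinded triplication harness

Each subject's tractogram appears three times: untouched, mirrored about
the grid's mid-X plane (an exact world-space involution), and translated by
a whole number of voxels (exactly invertible). A symmetric segmentation
protocol and the absence of an absolute coordinate frame make the three
tasks indistinguishable to the rater; seeded hex names blind them.

De-randomization resolves each returned bundle against the
forward-transformed parent in the variant's own space. Triplication
preserves streamline order, so variant indices equal original indices and
the round trip — triplicate, segment, de-randomize, fuse — recovers a
geometry-defined selection exactly, with no floating-point inverse
transform in the identity path. The inverse world transforms are still
recorded in the manifest's JSON sidecar for map-level work.

**Fusion** of the three replicates is the union of their index sets by
default. The design intent of fusion is to keep a rater's own
replicate-to-replicate variability out of inter-rater scores; union
maximizes retained evidence and makes fused size monotone in the inputs.
Majority-of-3 and intersection are selectable alternatives, since "fused"
admits several readings.

Scoring: intra-rater scores compare all 3 unordered replicate pairs per
subject (5 subjects × 3 pairs = 15 values per rater per measure);
inter-rater scores compare fused bundles across all rater pairs, a rater's
score averaging its N−1 comparisons (self-comparison excluded); gold
scores compare each fused bundle with the expert-vote average segmentation,
adding the classification metrics. Left/right bundles are pooled into one
distribution per measure; the score table keeps a hemisphere column so a
per-hemisphere breakdown remains possible.

Reporting uses medians and IQRs (score distributions are bounded and
skewed), with quartiles by linear interpolation between order statistics
(`stats::quantile` type 7) — stated so results reproduce bit-for-bit.
Group contrasts use the two-sided Mann–Whitney U test: exact enumeration
over all group assignments when both samples have at most 8 values (exact
under ties, and two identical samples give p = 1), otherwise the normal
approximation with tie-corrected variance. The default significance
threshold is 0.01, configurable.

## The synthetic study and what it does (not) show

`makePhantom()` builds a vertically coherent, gently curving fan of core
streamlines around a common centreline tube (radial offsets capped at 2.5
voxels, widening towards the top) plus straight-chord distractors, on a
32³ grid at 1 mm isotropic by default — large enough that the tube,
centred and away from edges, forms one 26-connected support component, and
small enough that a full simulated study runs in seconds. Scale arguments
go up to ~10⁵ streamlines for realism when wanted.

`simulateRater()` makes independent Bernoulli decisions per streamline:
keep each core streamline with probability *p*, pick up each distractor
with probability *q*. Independence is a deliberate simplification — it
yields closed-form expectations that make the whole pipeline
self-calibrating. For two independent raters at spurious rate q = 0 over
*C* core streamlines, `E|A| = E|B| = Cp` and `E|A∩B| = Cp²`, so pairwise
streamline Dice concentrates at *p*; with union fusion of three replicates
the effective keep rate becomes `1 − (1 − p)³`. Default study conditions:
5 subjects, triplicated to 15 anonymized datasets; expert raters
`p = 0.9, q = 0.01`, nonexperts `p = 0.9, q = 0.10` — same selection
fidelity on the true bundle, an order of magnitude more spurious inclusion,
which reproduces the expected signatures (nonexpert bundles bigger; their
precision against the gold standard lower; sensitivity comparable).

What passing these simulations does **not** show: real raters do not make
independent per-streamline errors — they move ROI boundaries, which
correlates errors spatially and inflates volume-level disagreement relative
to this model; the phantom's geometry is far simpler than any real
pathway; and scanner/tracking variability is out of scope entirely (inputs
are assumed co-registered). A correlated error mode and real-data inputs
through the TRK/TCK readers are the escape hatches.

## Numerical choices and degenerate inputs

* Dice/Jaccard of empty pairs: 1 (flagged); empty vs non-empty: 0.
* Metrics with zero denominators are returned `NA` and listed in an
  `undefined` attribute, never silently dropped or zeroed.
* Vote thresholds outside `[1, n]` and mixed parents/grids are errors.
* Resolution failures report how many bundle streamlines went unmatched;
  duplicate geometry is claimed lowest-parent-index-first.
* All simulation entry points take explicit integer seeds, restore the
  caller's RNG state, and derive child seeds below 2³¹.
* Map I/O writes integer dtypes (int32 counts, uint8 masks) so NIfTI round
  trips are bit-exact; affines are stored in qform and sform.

## Problem sizes used in the checks

The shipped tests and the acceptance script run the worked example
(2×5 grid), oracle comparisons over 10-element universes and 4³ maps,
parameter recovery at 1000 core streamlines with 30 seed pairs per keep
probability, and a full simulated study at 5 subjects × (11 experts + 13
nonexperts) with 200 core + 100 distractor streamlines per phantom —
chosen so the whole suite completes in about a minute on one CPU while
keeping Monte-Carlo error well inside the asserted tolerances.

## Limitations

* Majority-style voting only; latent-truth label fusion (STAPLE-like) is
  out of scope.
* No endpoint/termination maps, no fractional-occupancy voxelization.
* No nonlinear registration: inputs must already share a space; the only
  transforms implemented are the harness's own flip and integer-voxel
  translation.
* Streamline identity across *different* parent tractograms is undefined
  here; inter-subject comparisons need a common parent or voxel-level
  measures.
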