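# bundlerepro

Rater agreement for manual white-matter bundle segmentation from diffusion
MRI tractography.

When several raters (or one rater, repeatedly) dissect the same anatomical
bundle out of a shared whole-brain tractogram, how much do their bundles
agree — and does the answer depend on whether you compare the *streamlines*
they picked or the *volume* those streamlines occupy? `bundlerepro`
implements the full measurement machinery for that question:

* **Two representations of a bundle.** A segmentation is a subset of the
  parent tractogram's streamlines (a `Selection` of indices), and at the
  same time a voxel image: a *density map* counting distinct streamlines
  per voxel, reduced to a binary support mask. The two views can disagree
  dramatically — two raters may select almost disjoint streamline sets that
  still trace out nearly the same volume.
* **Agreement measures.** Dice `2|A∩B|/(|A|+|B|)` and Jaccard `|A∩B|/|A∪B|`
  in both representations, Pearson correlation of density maps, and
  confusion-based classification metrics against a reference segmentation —
  sensitivity, specificity, precision, accuracy, Youden index
  `J = sens + spec − 1`, and Cohen's kappa `(p_o − p_e)/(1 − p_e)`. With
  whole-tractogram or whole-grid universes the true negatives dominate, so
  specificity and accuracy saturate near 1 and kappa converges to Dice.
* **Vote-based consensus.** Per-element rater vote maps over streamlines or
  voxels; thresholding at 1-of-N gives the union, N-of-N the intersection,
  and a majority vote (e.g. 6 of 11) the *average segmentation* used as a
  pragmatic gold standard — explicitly not ground-truth anatomy.
* **A blinded triplication study harness.** Each subject's tractogram is
  presented three times (untouched, mirrored in X, translated by whole
  voxels) under random names; the manifest de-randomizes returned bundles,
  replicates are fused, and intra-rater, inter-rater and gold-standard
  score tables are produced with median/IQR summaries and Mann–Whitney
  group comparisons.
* **A synthetic phantom and rater simulator**, so the entire pipeline runs
  and is testable without any imaging data: a tube-and-fan phantom bundle
  with distractor clutter, and Bernoulli raters that keep each true-bundle
  streamline with probability *p* and pick up each distractor with
  probability *q* (pairwise streamline Dice between independent raters then
  has expectation *p*, which makes the simulator self-calibrating).

File formats: TRK and TCK tractograms (read/write, converted to a single
internal world-mm RAS convention), NIfTI-1 density maps and masks.

## Worked example

The didactic case: a 2×5 voxel grid with two different single-streamline
bundles whose masks cover 5 and 3 voxels, sharing 3.

```r
library(bundlerepro)

grid <- ReferenceGrid(c(5L, 2L, 1L), diag(4))
toy  <- Tractogram(list(cbind(0:4, 1, 0), cbind(2:4, 1, 0)), grid)
a <- Selection(0L, toy)   # 5-voxel streamline
b <- Selection(1L, toy)   # 3-voxel streamline

streamlineDice(a, b)
#> [1] 0
voxelDice(binaryMask(densityMap(toy, a, mode = "points")),
          binaryMask(densityMap(toy, b, mode = "points")))
#> [1] 0.75
```

Different streamlines mean streamline-wise Dice 0, yet the voxel-wise Dice
is 2·3/(5+3) = 0.75: overlap depends on the representation.

A miniature end-to-end study:

```r
study <- simulateStudy(nSubjects = 2, nExperts = 3, nNonexperts = 2,
                       nCore = 60, nDistractor = 30, seed = 7)
out <- runStudy(study)
head(out$summary[, 1:6], 4)
#>   comparison          measure     group    median        iqr  n
#> 1      intra dice_streamlines    expert 0.8950267 0.02835696 18
#> 2      intra dice_streamlines nonexpert 0.8610039 0.02905152 12
#> 3      intra      dice_voxels    expert 0.9605861 0.04011979 18
#> 4      intra      dice_voxels nonexpert 0.8980158 0.02775923 12
```

Each row is the median and IQR of one score distribution (here: 3 replicate
pairs × subjects per rater for `intra`), with a Mann–Whitney p-value
comparing the expert and nonexpert groups alongside.

## Command-line use

A thin CLI over the same functions is installed at
`inst/scripts/bundlerepro`:

```sh
bundlerepro convert   --in X.tck --out X.trk --grid ref.nii.gz
bundlerepro voxelize  --parent t.trk --bundle b.trk --grid ref.nii.gz --out d.nii.gz
bundlerepro score     --parent t.trk --a a.trk --b b.trk --grid ref.nii.gz --out report.json
bundlerepro consensus --parent t.trk --bundles r1.trk,r2.trk --grid ref.nii.gz --min-vote 6 --out-prefix gold
bundlerepro simulate  --subjects 5 --experts 11 --nonexperts 13 --seed 42 --out study/
```

See `vignettes/bundle-reproducibility.Rmd` for the methods account: model
assumptions, parameter choices, numerical conventions and limitations.
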