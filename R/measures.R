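# Pairwise agreement measures in both bundle representations.
#
# Empty-vs-empty convention: Dice and Jaccard of two empty sets are 1
# (perfect agreement on selecting nothing), so m(a, a) = 1 holds for every
# input; empty vs non-empty is 0.

diceFromCounts <- function(nInter, nA, nB) {
  if (nA + nB == 0) return(1)
  2 * nInter / (nA + nB)
}

jaccardFromCounts <- function(nInter, nUnion) {
  if (nUnion == 0) return(1)
  nInter / nUnion
}

#' Streamline-wise Dice coefficient
#'
#' `2 |A n B| / (|A| + |B|)` over the two selections' index sets. Two
#' bundles with no streamline in common score 0 even if they occupy almost
#' the same volume — the streamline representation is far stricter than the
#' voxel one, which is the central contrast this package quantifies.
#'
#' @param a,b [Selection-class] objects on the same parent.
#' @return Dice coefficient in `[0, 1]`.
#' @seealso [voxelDice()], [jaccardIndex()]
#' @export
streamlineDice <- function(a, b) {
  stopifnot(is(a, "Selection"), is(b, "Selection"))
  checkSameParent(a, b)
  diceFromCounts(length(intersect(a@indices, b@indices)),
                 length(a@indices), length(b@indices))
}

#' Voxel-wise Dice coefficient
#'
#' `2 |A n B| / (|A| + |B|)` over the support voxels of two binary masks on
#' the same grid. Density maps are reduced to their support first.
#'
#' @param a,b [BinaryMask-class] (or [DensityMap-class]) objects on the same
#'   grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
voxelDice <- function(a, b) {
  a <- binaryMask(a); b <- binaryMask(b)
  if (!sameGrid(a@grid, b@grid)) stop("masks are on different grids")
  diceFromCounts(sum(a@support & b@support),
                 sum(a@support), sum(b@support))
}

#' Jaccard index (both representations)
#'
#' `|A n B| / |A u B|` over streamline index sets or mask supports,
#' depending on the argument types. Related to Dice by `D = 2J / (1 + J)`.
#'
#' @param a,b two [Selection-class] objects (same parent) or two
#'   [BinaryMask-class]/[DensityMap-class] objects (same grid).
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccardIndex <- function(a, b) {
  if (is(a, "Selection") && is(b, "Selection")) {
    checkSameParent(a, b)
    nI <- length(intersect(a@indices, b@indices))
    nU <- length(a@indices) + length(b@indices) - nI
    return(jaccardFromCounts(nI, nU))
  }
  a <- binaryMask(a); b <- binaryMask(b)
  if (!sameGrid(a@grid, b@grid)) stop("masks are on different grids")
  jaccardFromCounts(sum(a@support & b@support), sum(a@support | b@support))
}

#' Pearson correlation of two density maps
#'
#' Correlates the per-voxel streamline counts of two density maps over a
#' chosen support. The default support is the union of the two maps'
#' nonzero voxels: correlating over the full grid lets the overwhelming
#' number of shared zero voxels inflate r towards 1.
#'
#' @param a,b [DensityMap-class] objects on the same grid.
#' @param support `"union"` (default: voxels nonzero in either map),
#'   `"mask"` (a supplied [BinaryMask-class]), or `"grid"` (all voxels).
#' @param mask a [BinaryMask-class], required when `support = "mask"`.
#' @return Pearson r in `[-1, 1]`.
#' @export
densityCorrelation <- function(a, b, support = c("union", "mask", "grid"),
                               mask = NULL) {
  support <- match.arg(support)
  stopifnot(is(a, "DensityMap"), is(b, "DensityMap"))
  if (!sameGrid(a@grid, b@grid)) stop("density maps are on different grids")
  sel <- switch(support,
    union = a@counts > 0L | b@counts > 0L,
    grid  = array(TRUE, dim = dim(a@counts)),
    mask  = {
      if (is.null(mask) || !is(mask, "BinaryMask"))
        stop("support = 'mask' requires a BinaryMask in 'mask'")
      if (!sameGrid(mask@grid, a@grid)) stop("mask is on a different grid")
      mask@support
    })
  x <- as.numeric(a@counts[sel])
  y <- as.numeric(b@counts[sel])
  if (length(x) < 2L)
    stop("correlation support has fewer than 2 voxels")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("density correlation undefined: zero variance on the chosen support")
  cor(x, y)
}

#' Confusion counts of a segmentation against a reference
#'
#' Classifies every element of a stated universe as TP/FP/FN/TN given a
#' predicted segmentation and a reference ("gold standard") segmentation.
#' For selections the default universe is every streamline of the parent
#' tractogram; for masks, every voxel of the grid. Because bundles occupy a
#' tiny fraction of either universe, TN dwarfs the other cells, which
#' pushes specificity and accuracy towards 1 and makes kappa approach Dice.
#'
#' @param pred,gold two [Selection-class] objects (same parent) or two
#'   [BinaryMask-class]/[DensityMap-class] objects (same grid).
#' @param universe for selections: the parent streamline count (or a
#'   `Tractogram`), or `"support"` to restrict to `pred u gold`; for masks:
#'   `"grid"` (default), `"support"`, or a [BinaryMask-class] universe.
#' @return A [ConfusionCounts-class].
#' @export
confusionCounts <- function(pred, gold, universe = NULL) {
  if (is(pred, "Selection") && is(gold, "Selection")) {
    checkSameParent(pred, gold)
    tp <- length(intersect(pred@indices, gold@indices))
    fp <- length(pred@indices) - tp
    fn <- length(gold@indices) - tp
    if (is.null(universe))
      stop("supply the universe for selections: the parent Tractogram, its streamline count, or 'support'")
    n <- if (is(universe, "Tractogram")) nStreamlines(universe)
         else if (identical(universe, "support"))
           length(union(pred@indices, gold@indices))
         else as.numeric(universe)
    used <- max(c(pred@indices, gold@indices, -1L)) + 1L
    if (n < used)
      stop(sprintf("universe size %g smaller than the largest index + 1 (%d)",
                   n, used))
    return(ConfusionCounts(tp, fp, fn, n - tp - fp - fn, n))
  }
  pred <- binaryMask(pred); gold <- binaryMask(gold)
  if (!sameGrid(pred@grid, gold@grid)) stop("masks are on different grids")
  if (is.null(universe)) universe <- "grid"
  u <- if (is(universe, "BinaryMask")) {
    if (!sameGrid(universe@grid, pred@grid)) stop("universe mask grid mismatch")
    universe@support
  } else if (identical(universe, "support")) {
    pred@support | gold@support
  } else if (identical(universe, "grid")) {
    array(TRUE, dim = dim(pred@support))
  } else stop("invalid universe for masks")
  if (any((pred@support | gold@support) & !u))
    stop("prediction or reference extends outside the chosen universe")
  p <- pred@support[u]; g <- gold@support[u]
  ConfusionCounts(sum(p & g), sum(p & !g), sum(!p & g), sum(!p & !g))
}

#' Classification metrics from confusion counts
#'
#' Sensitivity, specificity, precision, accuracy, the Youden index
#' (sensitivity + specificity - 1) and Cohen's kappa (chance-corrected
#' accuracy, `(p_o - p_e) / (1 - p_e)` with the expected agreement `p_e`
#' computed from the marginals). Metrics whose denominator is zero are
#' returned as `NA` and listed in the `"undefined"` attribute rather than
#' propagated silently.
#'
#' With TP, FP and FN fixed and TN growing without bound — the regime of
#' whole-tractogram or whole-grid universes — kappa converges to the Dice
#' coefficient of the two segmentations.
#'
#' @param x a [ConfusionCounts-class].
#' @return Named numeric vector with elements `sensitivity`, `specificity`,
#'   `precision`, `accuracy`, `youden`, `kappa`; undefined entries are `NA`
#'   with their names in `attr(, "undefined")`.
#' @export
classificationMetrics <- function(x) {
  stopifnot(is(x, "ConfusionCounts"))
  tp <- x@TP; fp <- x@FP; fn <- x@FN; tn <- x@TN
  total <- x@universe
  if (total == 0) stop("empty universe: no elements to classify")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  prec <- safe(tp, tp + fp)
  acc <- (tp + tn) / total
  youden <- sens + spec - 1
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / total^2
  kappa <- if (pe == 1) NA_real_ else (acc - pe) / (1 - pe)
  out <- c(sensitivity = sens, specificity = spec, precision = prec,
           accuracy = acc, youden = youden, kappa = kappa)
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' Full pairwise comparison report
#'
#' Convenience wrapper computing Dice and Jaccard in both representations
#' plus the density-map correlation for one pair of bundles.
#'
#' @param parent the shared parent [Tractogram-class].
#' @param a,b [Selection-class] objects on `parent`.
#' @param mode voxelization mode passed to [densityMap()].
#' @return A one-row `data.frame` with columns `dice_streamlines`,
#'   `jaccard_streamlines`, `dice_voxels`, `jaccard_voxels`,
#'   `density_correlation`.
#' @export
compareBundles <- function(parent, a, b, mode = "segments") {
  da <- densityMap(parent, a, mode = mode)
  db <- densityMap(parent, b, mode = mode)
  r <- tryCatch(densityCorrelation(da, db), error = function(e) NA_real_)
  data.frame(
    dice_streamlines = streamlineDice(a, b),
    jaccard_streamlines = jaccardIndex(a, b),
    dice_voxels = voxelDice(da, db),
    jaccard_voxels = jaccardIndex(binaryMask(da), binaryMask(db)),
    density_correlation = r)
}
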