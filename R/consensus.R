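# Vote-based consensus ("average segmentation") across raters.
#
# The thresholded consensus is deliberately labelled an average
# segmentation: it is the best approximation of what the rater group agrees
# on, not ground-truth anatomy.

#' Build a vote map from rater segmentations
#'
#' Counts, for every element of the universe (parent streamlines or grid
#' voxels), how many of the input segmentations contain it. Normalizing by
#' the number of raters gives a probability-map view (`normalized = TRUE`
#' in [voteCounts()] terms: `voteCounts(v) / nRaters(v)`).
#'
#' @param inputs a list of [Selection-class] objects (all on one parent) or
#'   of [BinaryMask-class]/[DensityMap-class] objects (all on one grid).
#' @param parent the parent [Tractogram-class]; required for selections to
#'   fix the universe size.
#' @return A [VoteMap-class] over the matching universe.
#' @examples
#' g <- ReferenceGrid(c(8L, 8L, 8L))
#' t <- Tractogram(replicate(5, cbind(0:2, 0, 0), simplify = FALSE), g)
#' v <- voteMap(list(Selection(c(0L, 1L), t), Selection(c(1L, 2L), t)), t)
#' voteCounts(v)  # 1 2 1 0 0
#' @export
voteMap <- function(inputs, parent = NULL) {
  if (length(inputs) < 1L) stop("at least one rater input is required")
  if (all(vapply(inputs, is, logical(1), "Selection"))) {
    if (is.null(parent) || !is(parent, "Tractogram"))
      stop("streamline vote maps need the parent Tractogram")
    pid <- tractId(parent)
    ok <- vapply(inputs, function(s) identical(s@parentId, pid), logical(1))
    if (!all(ok)) stop("all selections must share the same parent")
    votes <- integer(nStreamlines(parent))
    for (s in inputs) {
      if (length(s@indices) && max(s@indices) >= length(votes))
        stop("selection indices out of range for parent")
      votes[s@indices + 1L] <- votes[s@indices + 1L] + 1L
    }
    return(new("VoteMap", representation = "streamline", votes = votes,
               nRaters = length(inputs), parentId = pid, grid = NULL))
  }
  masks <- lapply(inputs, binaryMask)
  grid <- masks[[1]]@grid
  votes <- array(0L, dim = as.integer(grid@shape))
  for (m in masks) {
    if (!sameGrid(m@grid, grid)) stop("all masks must share the same grid")
    votes <- votes + m@support
  }
  storage.mode(votes) <- "integer"
  new("VoteMap", representation = "voxel", votes = votes,
      nRaters = length(masks), parentId = NA_character_, grid = grid)
}

#' Threshold a vote map into a consensus segmentation
#'
#' Keeps the elements voted for by at least `minVote` raters. `minVote = 1`
#' reproduces the exact union of the inputs and `minVote = nRaters` their
#' exact intersection; increasing the threshold only ever shrinks the
#' result. A fractional threshold `r` strictly between 0 and 1 is converted
#' to `ceiling(r * nRaters)`, so `r > 0.5` is a majority vote (6 of 11
#' raters, for example).
#'
#' @param v a [VoteMap-class].
#' @param minVote integer vote count in `[1, nRaters]`, or a ratio strictly
#'   between 0 and 1.
#' @return A [Selection-class] (streamline universe) or [BinaryMask-class]
#'   (voxel universe).
#' @export
thresholdVote <- function(v, minVote) {
  stopifnot(is(v, "VoteMap"))
  k <- if (length(minVote) == 1L && minVote > 0 && minVote < 1)
    as.integer(ceiling(minVote * v@nRaters)) else as.integer(minVote)
  if (is.na(k) || k < 1L || k > v@nRaters)
    stop(sprintf("minVote must give a threshold in [1, %d], got %s",
                 v@nRaters, format(minVote)))
  if (v@representation == "streamline")
    Selection(which(v@votes >= k) - 1L, v@parentId)
  else
    new("BinaryMask", grid = v@grid, support = v@votes >= k)
}

#' Build the vote-thresholded average segmentation in both representations
#'
#' From one list of rater selections, builds the streamline-universe and the
#' voxel-universe consensus independently: the streamline consensus
#' thresholds streamline votes; the voxel consensus thresholds the voxel
#' votes of the per-rater masks. The voxel consensus is *not* the mask of
#' the streamline consensus — the two universes are voted separately.
#'
#' @param inputs list of [Selection-class] objects on one parent.
#' @param parent the parent [Tractogram-class].
#' @param minVote vote threshold (count or ratio), as in [thresholdVote()].
#'   The classic majority rule with 11 raters is `minVote = 6`.
#' @param mode voxelization mode for the per-rater masks.
#' @return A list with elements `streamline` ([Selection-class]), `voxel`
#'   ([BinaryMask-class]), and the two [VoteMap-class] objects
#'   (`streamline_votes`, `voxel_votes`).
#' @export
buildGoldStandard <- function(inputs, parent, minVote, mode = "segments") {
  sv <- voteMap(inputs, parent)
  masks <- lapply(inputs, function(s)
    binaryMask(densityMap(parent, s, mode = mode)))
  vv <- voteMap(masks)
  list(streamline = thresholdVote(sv, minVote),
       voxel = thresholdVote(vv, minVote),
       streamline_votes = sv,
       voxel_votes = vv)
}
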