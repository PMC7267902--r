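#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats cor median quantile rnorm runif pnorm setNames
#' @importFrom utils combn head
NULL

## ---------------------------------------------------------------------------
## ReferenceGrid
## ---------------------------------------------------------------------------

#' Reference voxel grid
#'
#' A `ReferenceGrid` ties every voxel-level object (density maps, binary
#' masks, vote maps) and every tractogram to a common anatomical space. It is
#' the information carried by a NIfTI header: the grid dimensions and the
#' 4x4 affine mapping 0-based voxel indices (voxel centers at integer
#' coordinates) to world coordinates in mm, RAS orientation.
#'
#' A world point belongs to the voxel whose half-open cube
#' `[i - 0.5, i + 0.5)` (in voxel coordinates, per axis) contains it.
#'
#' @slot shape integer(3), voxels per axis; all positive.
#' @slot affine 4x4 numeric matrix, voxel-index to world-mm transform;
#'   must be invertible with positive voxel volume.
#'
#' @param shape integer(3) grid dimensions.
#' @param affine 4x4 voxel-to-world affine. Defaults to 1 mm isotropic voxels
#'   centred on the origin.
#' @return A `ReferenceGrid` object.
#' @examples
#' g <- ReferenceGrid(c(32L, 32L, 32L))
#' voxelVolume(g)
#' @export
setClass("ReferenceGrid",
  representation(shape = "integer", affine = "matrix"))

setValidity("ReferenceGrid", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(is.na(object@shape)) ||
      any(object@shape < 1L))
    msg <- c(msg, "'shape' must be 3 positive integers")
  a <- object@affine
  if (!is.numeric(a) || !identical(dim(a), c(4L, 4L)) || any(!is.finite(a)))
    msg <- c(msg, "'affine' must be a finite 4x4 numeric matrix")
  else {
    d <- det(a[1:3, 1:3])
    if (!is.finite(d) || abs(d) < .Machine$double.eps)
      msg <- c(msg, "'affine' must be invertible")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname ReferenceGrid-class
#' @export
ReferenceGrid <- function(shape, affine = NULL) {
  shape <- as.integer(shape)
  if (is.null(affine)) {
    affine <- diag(4)
    affine[1:3, 4] <- -(shape - 1) / 2
  }
  new("ReferenceGrid", shape = shape, affine = affine)
}

#' @describeIn ReferenceGrid-class volume of one voxel in mm^3
#'   (absolute determinant of the 3x3 block).
#' @param grid a `ReferenceGrid`.
#' @export
voxelVolume <- function(grid) {
  stopifnot(is(grid, "ReferenceGrid"))
  abs(det(grid@affine[1:3, 1:3]))
}

#' @describeIn ReferenceGrid-class grid dimensions (voxels per axis).
#' @export
gridShape <- function(grid) {
  stopifnot(is(grid, "ReferenceGrid"))
  grid@shape
}

#' @describeIn ReferenceGrid-class the 4x4 voxel-to-world affine.
#' @export
gridAffine <- function(grid) {
  stopifnot(is(grid, "ReferenceGrid"))
  grid@affine
}

sameGrid <- function(a, b, tol = 1e-5) {
  identical(a@shape, b@shape) && max(abs(a@affine - b@affine)) <= tol
}

## ---------------------------------------------------------------------------
## Tractogram
## ---------------------------------------------------------------------------

#' Tractogram: an ordered collection of streamlines
#'
#' A tractogram is an ordered list of streamlines, each an ordered polyline of
#' 3D points in world mm (RAS). The order is stable: a streamline's position
#' in the list is its identity, and bundle selections refer to these indices.
#' Every tractogram carries the [ReferenceGrid-class] of its anatomical space.
#'
#' @slot streamlines list of numeric matrices, each n x 3 with n >= 2,
#'   finite world-mm coordinates.
#' @slot grid a [ReferenceGrid-class].
#' @slot id opaque character label used to match [Selection-class] objects to
#'   their parent.
#'
#' @param streamlines list of n x 3 coordinate matrices.
#' @param grid a `ReferenceGrid`.
#' @param id character label (default `"tractogram"`).
#' @return A `Tractogram`.
#' @examples
#' g <- ReferenceGrid(c(10L, 10L, 10L))
#' t <- Tractogram(list(cbind(0:3, 0, 0)), g, id = "toy")
#' nStreamlines(t)
#' @export
setClass("Tractogram",
  representation(streamlines = "list", grid = "ReferenceGrid",
                 id = "character"))

setValidity("Tractogram", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id))
    msg <- c(msg, "'id' must be a single non-NA string")
  ok <- vapply(object@streamlines, function(s) {
    is.matrix(s) && is.numeric(s) && ncol(s) == 3L && nrow(s) >= 2L &&
      all(is.finite(s))
  }, logical(1))
  if (!all(ok))
    msg <- c(msg, sprintf(
      "%d streamline(s) are not finite numeric matrices with >= 2 points x 3 coords",
      sum(!ok)))
  if (length(msg)) msg else TRUE
})

#' @rdname Tractogram-class
#' @export
Tractogram <- function(streamlines, grid, id = "tractogram") {
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    dimnames(s) <- NULL
    s
  })
  new("Tractogram", streamlines = streamlines, grid = grid,
      id = as.character(id))
}

#' @describeIn Tractogram-class number of streamlines.
#' @param x a `Tractogram`.
#' @export
nStreamlines <- function(x) {
  stopifnot(is(x, "Tractogram"))
  length(x@streamlines)
}

#' @describeIn Tractogram-class list of streamline coordinate matrices;
#'   optionally only those at `which` (1-based).
#' @param which optional integer vector of 1-based streamline positions.
#' @export
streamlines <- function(x, which = NULL) {
  stopifnot(is(x, "Tractogram"))
  if (is.null(which)) x@streamlines else x@streamlines[which]
}

#' @describeIn Tractogram-class the tractogram's opaque label.
#' @export
tractId <- function(x) {
  stopifnot(is(x, "Tractogram"))
  x@id
}

## ---------------------------------------------------------------------------
## Selection
## ---------------------------------------------------------------------------

#' Selection: a rater's bundle as parent streamline indices
#'
#' The streamline-representation of a segmented bundle: the strictly
#' increasing 0-based indices of the selected streamlines in the parent
#' tractogram. All streamline-wise comparison measures operate on these
#' index sets.
#'
#' @slot parentId label of the parent [Tractogram-class].
#' @slot indices strictly increasing 0-based integer indices.
#'
#' @param indices integer vector of 0-based streamline indices (any order;
#'   duplicates are an error).
#' @param parent either a parent `Tractogram` (its id and count are used for
#'   validation) or a character parent id.
#' @param nParent optional parent streamline count used for bounds checking
#'   when `parent` is a bare id.
#' @return A `Selection`.
#' @examples
#' g <- ReferenceGrid(c(10L, 10L, 10L))
#' t <- Tractogram(list(cbind(0:2, 0, 0), cbind(0, 0:2, 0)), g)
#' Selection(c(0L, 1L), t)
#' @export
setClass("Selection",
  representation(parentId = "character", indices = "integer"))

setValidity("Selection", function(object) {
  msg <- character()
  if (length(object@parentId) != 1L || is.na(object@parentId))
    msg <- c(msg, "'parentId' must be a single non-NA string")
  idx <- object@indices
  if (any(is.na(idx)) || any(idx < 0L))
    msg <- c(msg, "'indices' must be non-negative and non-NA")
  if (anyDuplicated(idx))
    msg <- c(msg, "'indices' must be unique")
  if (is.unsorted(idx, strictly = TRUE) && length(idx) > 1L)
    msg <- c(msg, "'indices' must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @rdname Selection-class
#' @export
Selection <- function(indices, parent, nParent = NULL) {
  idx <- sort(unique(as.integer(indices)))
  if (length(idx) != length(indices))
    stop("selection indices must be unique")
  if (is(parent, "Tractogram")) {
    nParent <- nStreamlines(parent)
    parentId <- tractId(parent)
  } else {
    parentId <- as.character(parent)
  }
  if (!is.null(nParent) && length(idx) && max(idx) >= nParent)
    stop(sprintf("selection index %d out of range for parent with %d streamlines",
                 max(idx), nParent))
  new("Selection", parentId = parentId, indices = idx)
}

#' @describeIn Selection-class the 0-based indices.
#' @param x a `Selection`.
#' @export
selectionIndices <- function(x) {
  stopifnot(is(x, "Selection"))
  x@indices
}

#' @describeIn Selection-class the parent tractogram label.
#' @export
parentId <- function(x) {
  stopifnot(is(x, "Selection"))
  x@parentId
}

#' @describeIn Selection-class number of selected streamlines.
#' @export
selectionSize <- function(x) {
  stopifnot(is(x, "Selection"))
  length(x@indices)
}

checkSameParent <- function(a, b) {
  if (!identical(a@parentId, b@parentId))
    stop(sprintf("selections have different parents ('%s' vs '%s')",
                 a@parentId, b@parentId))
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## DensityMap / BinaryMask
## ---------------------------------------------------------------------------

#' Streamline density map
#'
#' The voxel representation of a bundle: for each voxel of the reference grid,
#' the number of *distinct* streamlines of the selection that touch it. A
#' streamline contributes at most 1 to a voxel no matter how many of its
#' points or segments fall inside.
#'
#' @slot grid a [ReferenceGrid-class].
#' @slot counts 3D integer array with `dim == gridShape(grid)`.
#' @slot nClipped number of streamline points that fell outside the grid and
#'   were ignored.
#'
#' @seealso [densityMap()], [binaryMask()], [writeMap()]
#' @export
setClass("DensityMap",
  representation(grid = "ReferenceGrid", counts = "array",
                 nClipped = "integer"))

setValidity("DensityMap", function(object) {
  msg <- character()
  if (!identical(dim(object@counts), as.integer(object@grid@shape)))
    msg <- c(msg, "'counts' dimensions must match the grid shape")
  if (any(object@counts < 0L))
    msg <- c(msg, "'counts' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Binary bundle mask
#'
#' The support of a [DensityMap-class]: TRUE where at least one streamline
#' touches the voxel. All voxel-wise overlap measures (Dice, Jaccard,
#' confusion counts) operate on these supports.
#'
#' @slot grid a [ReferenceGrid-class].
#' @slot support 3D logical array with `dim == gridShape(grid)`.
#'
#' @seealso [binaryMask()], [voxelDice()]
#' @export
setClass("BinaryMask",
  representation(grid = "ReferenceGrid", support = "array"))

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (!identical(dim(object@support), as.integer(object@grid@shape)))
    msg <- c(msg, "'support' dimensions must match the grid shape")
  if (!is.logical(object@support))
    msg <- c(msg, "'support' must be logical")
  if (length(msg)) msg else TRUE
})

#' @describeIn DensityMap-class the 3D array of per-voxel streamline counts.
#' @param x a `DensityMap` or `BinaryMask`.
#' @export
mapCounts <- function(x) {
  stopifnot(is(x, "DensityMap"))
  x@counts
}

#' @describeIn BinaryMask-class the 3D logical support array.
#' @export
maskSupport <- function(x) {
  stopifnot(is(x, "BinaryMask"))
  x@support
}

#' Grid accessor for voxel-level objects
#'
#' @param x a `Tractogram`, `DensityMap`, `BinaryMask` or `VoteMap`.
#' @return the object's [ReferenceGrid-class] (or `NULL` for a
#'   streamline-universe `VoteMap`).
#' @export
mapGrid <- function(x) {
  if (is(x, "VoteMap")) return(x@grid)
  stopifnot(is(x, "Tractogram") || is(x, "DensityMap") || is(x, "BinaryMask"))
  x@grid
}

## ---------------------------------------------------------------------------
## VoteMap
## ---------------------------------------------------------------------------

#' Rater vote map
#'
#' Per-element rater vote counts over one of the two universes: the parent
#' tractogram's streamlines, or the voxels of a reference grid. Thresholding
#' a vote map ([thresholdVote()]) yields consensus selections; the 1-of-N
#' threshold is the union of the inputs, the N-of-N threshold their
#' intersection.
#'
#' @slot representation `"streamline"` or `"voxel"`.
#' @slot votes integer vector (length = parent streamline count) or 3D
#'   integer array matching the grid.
#' @slot nRaters number of rater inputs counted.
#' @slot parentId parent tractogram label (streamline universe; `NA`
#'   otherwise).
#' @slot grid a [ReferenceGrid-class] (voxel universe) or `NULL`.
#'
#' @seealso [voteMap()], [thresholdVote()], [buildGoldStandard()]
#' @export
setClass("VoteMap",
  representation(representation = "character", votes = "ANY",
                 nRaters = "integer", parentId = "character", grid = "ANY"))

setValidity("VoteMap", function(object) {
  msg <- character()
  if (!object@representation %in% c("streamline", "voxel"))
    msg <- c(msg, "'representation' must be 'streamline' or 'voxel'")
  v <- object@votes
  if (any(v < 0L) || any(v > object@nRaters))
    msg <- c(msg, "votes must lie in [0, nRaters]")
  if (object@representation == "voxel") {
    if (!is(object@grid, "ReferenceGrid"))
      msg <- c(msg, "voxel vote map needs a ReferenceGrid")
    else if (!identical(dim(v), as.integer(object@grid@shape)))
      msg <- c(msg, "votes array must match the grid shape")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn VoteMap-class the raw vote counts (vector or array).
#' @param x a `VoteMap`.
#' @export
voteCounts <- function(x) {
  stopifnot(is(x, "VoteMap"))
  x@votes
}

#' @describeIn VoteMap-class the number of raters counted.
#' @export
nRaters <- function(x) {
  stopifnot(is(x, "VoteMap"))
  x@nRaters
}

## ---------------------------------------------------------------------------
## ConfusionCounts
## ---------------------------------------------------------------------------

#' Confusion counts against an average ("gold standard") segmentation
#'
#' Element counts of the 2x2 confusion table between a predicted segmentation
#' and a reference over a stated universe (all parent streamlines, or all grid
#' voxels). By construction the reference contains no false positives or
#' negatives; the universe size drives the true-negative count, which in
#' whole-tractogram/whole-grid universes dwarfs everything else.
#'
#' @slot TP,FP,FN,TN non-negative counts; they sum to `universe`.
#' @slot universe universe size.
#'
#' @seealso [confusionCounts()], [classificationMetrics()]
#' @export
setClass("ConfusionCounts",
  representation(TP = "numeric", FP = "numeric", FN = "numeric",
                 TN = "numeric", universe = "numeric"))

setValidity("ConfusionCounts", function(object) {
  msg <- character()
  v <- c(object@TP, object@FP, object@FN, object@TN, object@universe)
  if (any(!is.finite(v)) || any(v < 0))
    msg <- c(msg, "all counts must be finite and non-negative")
  else if (abs(object@TP + object@FP + object@FN + object@TN -
               object@universe) > 1e-9)
    msg <- c(msg, "TP + FP + FN + TN must equal the universe size")
  if (length(msg)) msg else TRUE
})

#' @rdname ConfusionCounts-class
#' @param TP,FP,FN,TN non-negative counts.
#' @param universe universe size; default `TP + FP + FN + TN`.
#' @export
ConfusionCounts <- function(TP, FP, FN, TN, universe = TP + FP + FN + TN) {
  new("ConfusionCounts", TP = as.numeric(TP), FP = as.numeric(FP),
      FN = as.numeric(FN), TN = as.numeric(TN),
      universe = as.numeric(universe))
}

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ReferenceGrid", function(object) {
  cat(sprintf("ReferenceGrid %s, voxel volume %.4g mm^3\n",
              paste(object@shape, collapse = "x"), voxelVolume(object)))
})

setMethod("show", "Tractogram", function(object) {
  np <- vapply(object@streamlines, nrow, integer(1))
  cat(sprintf("Tractogram '%s': %d streamlines", object@id,
              length(object@streamlines)))
  if (length(np))
    cat(sprintf(", %d-%d points each", min(np), max(np)))
  cat(sprintf("\n  grid %s\n", paste(object@grid@shape, collapse = "x")))
})

setMethod("show", "Selection", function(object) {
  cat(sprintf("Selection of %d streamlines from parent '%s'\n",
              length(object@indices), object@parentId))
})

setMethod("show", "DensityMap", function(object) {
  cat(sprintf("DensityMap %s: %d support voxels, max count %d",
              paste(object@grid@shape, collapse = "x"),
              sum(object@counts > 0L), max(0L, object@counts)))
  if (object@nClipped > 0L)
    cat(sprintf(" (%d points clipped)", object@nClipped))
  cat("\n")
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask %s: %d support voxels\n",
              paste(object@grid@shape, collapse = "x"), sum(object@support)))
})

setMethod("show", "VoteMap", function(object) {
  cat(sprintf("VoteMap (%s universe): %d raters, max vote %d, support %d\n",
              object@representation, object@nRaters,
              max(0L, object@votes), sum(object@votes > 0L)))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%g FP=%g FN=%g TN=%g (universe %g)\n",
              object@TP, object@FP, object@FN, object@TN, object@universe))
})
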