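#' Descriptive measures of a bundle
#'
#' Per-bundle attributes read directly off a selection: streamline count,
#' occupied volume, mean streamline length and, when a scalar map such as FA
#' is supplied, the mean scalar over the bundle.
#'
#' Volume is the number of support voxels of the bundle's density map times
#' the voxel volume, reported in cm^3. Mean length is the mean polyline arc
#' length in mm. The mean scalar is by default the unweighted mean over the
#' binary support; with `weighted = TRUE` each voxel is weighted by its
#' streamline count.
#'
#' @param parent a [Tractogram-class].
#' @param sel a [Selection-class] on `parent`.
#' @param scalarMap optional [DensityMap-class]-shaped scalar image: either a
#'   NIfTI path or a numeric 3D array on the parent grid.
#' @param mode voxelization mode for the volume/support (see [densityMap()]).
#' @param weighted weight the scalar mean by streamline density.
#' @return A list with `streamline_count`, `volume_cm3`, `mean_length_mm`,
#'   and `mean_scalar` (NA when no map given). For an empty selection the
#'   count and volume are 0 and the means are `NA`.
#' @examples
#' g <- ReferenceGrid(c(16L, 16L, 16L))
#' t <- Tractogram(list(cbind(seq(0, 5, length.out = 11), 0, 0)), g)
#' bundleStats(t, Selection(0L, t))$mean_length_mm  # 5
#' @export
bundleStats <- function(parent, sel, scalarMap = NULL,
                        mode = "segments", weighted = FALSE) {
  stopifnot(is(parent, "Tractogram"), is(sel, "Selection"))
  n <- selectionSize(sel)
  if (n == 0L)
    return(list(streamline_count = 0L, volume_cm3 = 0,
                mean_length_mm = NA_real_, mean_scalar = NA_real_))
  d <- densityMap(parent, sel, mode = mode)
  lengths <- vapply(streamlines(parent, sel@indices + 1L), function(s)
    sum(sqrt(rowSums(diff(s)^2))), numeric(1))
  vol <- sum(d@counts > 0L) * voxelVolume(parent@grid) / 1000  # mm^3 -> cm^3
  meanScalar <- NA_real_
  if (!is.null(scalarMap)) {
    arr <- if (is.character(scalarMap)) {
      img <- RNifti::readNifti(scalarMap)
      a <- as.array(img); dim(a) <- dim(img)[1:3]; a
    } else scalarMap
    if (!identical(dim(arr), as.integer(parent@grid@shape)))
      stop("scalar map dimensions do not match the parent grid")
    vals <- arr[d@counts > 0L]
    w <- if (weighted) as.numeric(d@counts[d@counts > 0L])
         else rep(1, length(vals))
    meanScalar <- sum(vals * w) / sum(w)
  }
  list(streamline_count = n, volume_cm3 = vol,
       mean_length_mm = mean(lengths), mean_scalar = meanScalar)
}
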