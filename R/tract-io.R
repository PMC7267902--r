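# Tractogram file I/O: TRK (TrackVis) and TCK (MRtrix) formats.
#
# Internal convention: all streamline points in world mm, RAS. TRK stores
# points in voxel-scaled mm with the corner of voxel (0,0,0) at the origin
# (voxel center i sits at (i + 0.5) * voxel_size); they are converted to
# world mm on read via the header's vox_to_ras. TCK stores world mm natively.

TRK_HEADER_SIZE <- 1000L

padRaw <- function(s, n) {
  r <- charToRaw(s)
  if (length(r) > n) r <- r[seq_len(n)]
  c(r, raw(n - length(r)))
}

trkVoxelSize <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

readTrk <- function(path, grid = NULL, tol = 1e-3, id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(rawToChar(magic[1:5]), "TRACK"))
    stop(sprintf("'%s' is not a TRK file (bad magic)", path))
  dim3 <- readBin(con, "integer", 3L, size = 2L, endian = "little")
  voxelSize <- readBin(con, "double", 3L, size = 4L, endian = "little")
  readBin(con, "double", 3L, size = 4L, endian = "little")  # origin, unused
  nScalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  nProps <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  voxToRas <- matrix(readBin(con, "double", 16L, size = 4L,
                             endian = "little"), 4L, 4L, byrow = TRUE)
  readBin(con, "raw", 444L + 4L + 4L + 24L + 2L + 6L)
  nCount <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdrSize <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (hdrSize != TRK_HEADER_SIZE)
    stop(sprintf("corrupt TRK header in '%s' (hdr_size %d)", path, hdrSize))
  if (version >= 2L && all(voxToRas == 0))
    stop(sprintf("TRK file '%s' has an all-zero vox_to_ras affine", path))
  if (version < 2L || all(voxToRas == 0)) voxToRas <- diag(4)

  fileGrid <- ReferenceGrid(as.integer(dim3), voxToRas)
  if (!is.null(grid)) {
    if (!sameGrid(grid, fileGrid, tol = max(tol, 1e-3)))
      stop(sprintf("TRK header grid of '%s' does not match the supplied grid",
                   path))
    fileGrid <- grid  # keep the caller's double-precision affine
  }
  vs <- trkVoxelSize(fileGrid@affine)

  streamlines <- vector("list", max(nCount, 0L))
  i <- 0L
  repeat {
    np <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(np) == 0L) break
    if (np < 0L) stop(sprintf("corrupt TRK record in '%s'", path))
    vals <- readBin(con, "double", np * (3L + nScalars), size = 4L,
                    endian = "little")
    if (length(vals) < np * (3L + nScalars))
      stop(sprintf("truncated TRK file '%s'", path))
    if (nProps > 0L) readBin(con, "double", nProps, size = 4L,
                             endian = "little")
    m <- matrix(vals, ncol = 3L + nScalars, byrow = TRUE)[, 1:3, drop = FALSE]
    # voxmm -> voxel-center coords -> world
    m <- sweep(m, 2L, vs, "/") - 0.5
    i <- i + 1L
    streamlines[[i]] <- applyAffine(fileGrid@affine, m)
  }
  length(streamlines) <- i
  if (nCount > 0L && i != nCount)
    stop(sprintf("TRK file '%s' declares %d streamlines but contains %d",
                 path, nCount, i))
  Tractogram(streamlines, fileGrid,
             id = if (is.null(id)) basename(path) else id)
}

writeTrk <- function(t, path) {
  grid <- t@grid
  vs <- trkVoxelSize(grid@affine)
  inv <- solve(grid@affine)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(padRaw("TRACK", 6L), con)
  writeBin(as.integer(grid@shape), con, size = 2L, endian = "little")
  writeBin(as.numeric(vs), con, size = 4L, endian = "little")
  writeBin(numeric(3L), con, size = 4L, endian = "little")  # origin
  writeBin(0L, con, size = 2L, endian = "little")           # n_scalars
  writeBin(raw(200L), con)
  writeBin(0L, con, size = 2L, endian = "little")           # n_properties
  writeBin(raw(200L), con)
  writeBin(as.numeric(t(grid@affine)), con, size = 4L, endian = "little")
  writeBin(raw(444L), con)
  writeBin(padRaw("RAS", 4L), con)                          # voxel_order
  writeBin(raw(4L), con)                                    # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4L, endian = "little")
  writeBin(raw(2L + 6L), con)                               # pad1 + flags
  writeBin(length(t@streamlines), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")           # version
  writeBin(TRK_HEADER_SIZE, con, size = 4L, endian = "little")
  for (s in t@streamlines) {
    vox <- applyAffine(inv, s)                # voxel-center coords
    voxmm <- sweep(vox + 0.5, 2L, vs, "*")    # corner-origin voxel mm
    writeBin(nrow(s), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

readTck <- function(path, grid, id = NULL) {
  if (is.null(grid))
    stop("TCK files carry no voxel grid; supply a ReferenceGrid (e.g. from readMap(..., as = 'grid'))")
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1L, warn = FALSE)
  if (!identical(trimws(first), "mrtrix tracks"))
    stop(sprintf("'%s' is not a TCK file (bad magic)", path))
  offset <- NA_integer_
  datatype <- "Float32LE"
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop(sprintf("truncated TCK header in '%s'", path))
    if (identical(trimws(line), "END")) break
    kv <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) {
      key <- trimws(kv[2]); val <- trimws(kv[3])
      if (key == "file") {
        parts <- strsplit(val, "\\s+")[[1]]
        offset <- as.integer(parts[length(parts)])
      } else if (key == "datatype") datatype <- val
    }
  }
  if (is.na(offset)) stop(sprintf("TCK header of '%s' lacks a 'file' entry", path))
  if (!datatype %in% c("Float32LE", "Float32BE"))
    stop(sprintf("unsupported TCK datatype '%s'", datatype))
  endian <- if (datatype == "Float32LE") "little" else "big"
  seek(con, offset)
  vals <- readBin(con, "double", file.size(path), size = 4L, endian = endian)
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  streamlines <- list()
  start <- 1L
  for (r in seq_len(nrow(m))) {
    if (all(is.nan(m[r, ])) || all(is.infinite(m[r, ]))) {
      if (r > start)
        streamlines[[length(streamlines) + 1L]] <-
          m[start:(r - 1L), , drop = FALSE]
      start <- r + 1L
      if (all(is.infinite(m[r, ]))) break
    }
  }
  Tractogram(streamlines, grid, id = if (is.null(id)) basename(path) else id)
}

writeTck <- function(t, path) {
  ns <- length(t@streamlines)
  hdr <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ", ns, "\n")
  offset <- nchar(hdr) + nchar("file: . ") + 12L + nchar("\nEND\n")
  hdr <- paste0(hdr, "file: . ", formatC(offset, width = 12L), "\nEND\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  for (s in t@streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a tractogram from a TRK or TCK file
#'
#' Streamline coordinates are returned in world mm (RAS) regardless of the
#' on-disk convention: TRK's voxel-scaled storage is mapped through the
#' header affine, TCK is taken as world mm (its native convention). The
#' format is chosen by file extension.
#'
#' @param path a `.trk` or `.tck` file.
#' @param grid optional [ReferenceGrid-class]. Required for TCK (the format
#'   has no grid); for TRK it is checked against the header and, when
#'   consistent, used in place of the header's float32 affine.
#' @param id label for the resulting [Tractogram-class]; defaults to the
#'   file name.
#' @return A [Tractogram-class].
#' @seealso [writeTractogram()], [resolveSelection()]
#' @export
readTractogram <- function(path, grid = NULL, id = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    trk = readTrk(path, grid = grid, id = id),
    tck = readTck(path, grid = grid, id = id),
    stop(sprintf("unsupported tractogram extension '.%s' (use .trk or .tck)",
                 ext)))
}

#' Write a tractogram to TRK or TCK
#'
#' Coordinates survive a write/read round-trip to float32 precision
#' (better than 1e-3 mm at brain-scale coordinates); streamline count,
#' order and per-streamline point counts are preserved exactly.
#'
#' @param t a [Tractogram-class].
#' @param path output path.
#' @param format `"trk"` or `"tck"`; inferred from the extension by default.
#' @return `path`, invisibly.
#' @export
writeTractogram <- function(t, path, format = NULL) {
  stopifnot(is(t, "Tractogram"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("trk", "tck"))
  if (format == "trk") writeTrk(t, path) else writeTck(t, path)
  invisible(path)
}

streamlineKeys <- function(streamlines, tol) {
  vapply(streamlines, function(s)
    paste(as.integer(round(as.numeric(t(s)) / tol)), collapse = ","),
    character(1))
}

#' Resolve a file-based bundle to parent streamline indices
#'
#' Matches each streamline of `bundle` to exactly one streamline of `parent`
#' by coordinate identity: same point count, same order, every coordinate
#' within `tol` mm. Matching hashes coordinates rounded to `tol`, so it is
#' O(n) in the common case; streamlines that miss the hash (coordinates on a
#' rounding boundary after float32 storage) fall back to a direct search.
#'
#' When the parent contains geometrically identical streamlines (which a
#' rater's bundle may then contain more than once), matches are assigned
#' greedily to the lowest unclaimed parent index; the result is independent
#' of the order of streamlines in the bundle file.
#'
#' @param parent the shared parent [Tractogram-class] all raters segmented.
#' @param bundle a [Tractogram-class] whose streamlines are a subset of the
#'   parent's (e.g. read from a rater's returned file).
#' @param tol per-coordinate matching tolerance in mm.
#' @return A [Selection-class] on `parent`.
#' @export
resolveSelection <- function(parent, bundle, tol = 1e-3) {
  stopifnot(is(parent, "Tractogram"), is(bundle, "Tractogram"))
  parentKeys <- streamlineKeys(parent@streamlines, tol)
  lookup <- split(seq_along(parentKeys) - 1L, parentKeys)
  bundleKeys <- streamlineKeys(bundle@streamlines, tol)

  claimed <- integer(0)
  failed <- 0L
  # canonical processing order: by key, so file order cannot matter
  for (key in sort(unique(bundleKeys))) {
    need <- sum(bundleKeys == key)
    cand <- lookup[[key]]
    if (is.null(cand)) {
      # fallback: direct comparison against same-point-count parents
      b <- bundle@streamlines[[match(key, bundleKeys)]]
      cand <- which(vapply(parent@streamlines, function(p)
        nrow(p) == nrow(b) && max(abs(p - b)) <= tol, logical(1))) - 1L
    }
    cand <- sort(setdiff(cand, claimed))
    if (length(cand) < need) {
      failed <- failed + (need - length(cand))
      need <- length(cand)
    }
    claimed <- c(claimed, cand[seq_len(need)])
  }
  if (failed > 0L)
    stop(sprintf("%d bundle streamline(s) could not be matched to the parent tractogram",
                 failed))
  Selection(claimed, parent)
}
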