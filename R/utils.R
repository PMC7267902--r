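# internal geometry + RNG helpers

# apply a 4x4 affine to an n x 3 point matrix
applyAffine <- function(affine, pts) {
  out <- pts %*% t(affine[1:3, 1:3])
  out[, 1] <- out[, 1] + affine[1, 4]
  out[, 2] <- out[, 2] + affine[2, 4]
  out[, 3] <- out[, 3] + affine[3, 4]
  out
}

# world mm -> 0-based voxel indices (corner convention: voxel i spans
# [i - 0.5, i + 0.5) around its integer-center voxel coordinate)
worldToVoxel <- function(grid, pts) {
  vox <- applyAffine(solve(grid@affine), pts)
  matrix(as.integer(floor(vox + 0.5)), ncol = 3)
}

inGrid <- function(grid, vox) {
  vox[, 1] >= 0L & vox[, 1] < grid@shape[1] &
  vox[, 2] >= 0L & vox[, 2] < grid@shape[2] &
  vox[, 3] >= 0L & vox[, 3] < grid@shape[3]
}

# evaluate `expr` under a temporary seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# derive k child seeds from one master seed (keeps everything < 2^31)
childSeeds <- function(seed, k) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# seeded pseudo-anonymous hex names
anonNames <- function(n) {
  vapply(seq_len(n), function(i)
    paste(sprintf("%02x", sample.int(256L, 12L, replace = TRUE) - 1L),
          collapse = ""), character(1))
}
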