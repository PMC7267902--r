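# Fixtures and independent brute-force oracles used across the suite.
# Everything is generated in code; no data files.

# identity-affine grid: world coordinates == voxel coordinates
unitGrid <- function(shape = c(8L, 8L, 8L)) {
  ReferenceGrid(as.integer(shape), diag(4))
}

# a tractogram whose streamline i passes through the voxels listed in
# voxelRows[[i]] (n x 3 matrices of 0-based voxel indices), points at centers
tractFromVoxels <- function(voxelRows, shape = c(8L, 8L, 8L), id = "toy") {
  g <- unitGrid(shape)
  Tractogram(lapply(voxelRows, function(v) {
    v <- matrix(as.numeric(v), ncol = 3)
    if (nrow(v) == 1L) v <- rbind(v, v + c(1e-6, 0, 0))
    v
  }), g, id = id)
}

# the didactic 2x5-grid worked example: four streamlines, red/blue
# bit-identical, yellow covering 5 voxels, green 3, sharing 3
workedExample <- function() {
  rows <- list(
    red    = cbind(0:4, 0, 0),
    blue   = cbind(0:4, 0, 0),
    yellow = cbind(0:4, 1, 0),
    green  = cbind(2:4, 1, 0))
  tractFromVoxels(rows, shape = c(5L, 2L, 1L), id = "fig2")
}

# --- brute-force set oracles (membership-vector route) ---------------------

oracleSetCounts <- function(a, b, n) {
  ina <- (seq_len(n) - 1L) %in% a
  inb <- (seq_len(n) - 1L) %in% b
  list(tp = sum(ina & inb), fp = sum(ina & !inb),
       fn = sum(!ina & inb), tn = sum(!ina & !inb))
}

oracleDice <- function(a, b, n) {
  cc <- oracleSetCounts(a, b, n)
  if (length(a) + length(b) == 0L) return(1)
  2 * cc$tp / (length(a) + length(b))
}

oracleJaccard <- function(a, b, n) {
  cc <- oracleSetCounts(a, b, n)
  u <- cc$tp + cc$fp + cc$fn
  if (u == 0L) return(1)
  cc$tp / u
}

oracleKappa <- function(tp, fp, fn, tn) {
  tot <- tp + fp + fn + tn
  po <- (tp + tn) / tot
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / tot^2
  (po - pe) / (1 - pe)
}

oraclePearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# linear-interpolation quantile, written out by hand on the sorted vector
oracleQuantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (ifelse(lo + 2 > length(x), x[lo + 1],
                                 x[lo + 2]) - x[lo + 1])
}

# Mann-Whitney U by explicit concordant-pair counting
oracleU <- function(a, b) {
  u <- 0
  for (x in a) for (y in b)
    u <- u + (x > y) + 0.5 * (x == y)
  u
}

# densely sample a polyline and collect the 0-based voxels its samples hit:
# an independent route to the segment-traversal support (step small enough
# that no crossed voxel is skipped)
oracleSegmentVoxels <- function(pts, grid, step = 0.005) {
  inv <- solve(gridAffine(grid))
  vox <- character(0)
  for (i in seq_len(nrow(pts) - 1)) {
    p0 <- pts[i, ]; p1 <- pts[i + 1, ]
    n <- max(2L, ceiling(sqrt(sum((p1 - p0)^2)) / step))
    tt <- seq(0, 1, length.out = n)
    samp <- cbind(p0[1] + tt * (p1[1] - p0[1]),
                  p0[2] + tt * (p1[2] - p0[2]),
                  p0[3] + tt * (p1[3] - p0[3]))
    v <- floor((samp %*% t(inv[1:3, 1:3]) +
                 matrix(inv[1:3, 4], nrow(samp), 3, byrow = TRUE)) + 0.5)
    keep <- v[, 1] >= 0 & v[, 1] < gridShape(grid)[1] &
            v[, 2] >= 0 & v[, 2] < gridShape(grid)[2] &
            v[, 3] >= 0 & v[, 3] < gridShape(grid)[3]
    vox <- c(vox, apply(v[keep, , drop = FALSE], 1, paste, collapse = ","))
  }
  unique(vox)
}

maskVoxelKeys <- function(mask) {
  idx <- which(maskSupport(mask), arr.ind = TRUE) - 1L
  apply(idx, 1, paste, collapse = ",")
}

# 26-connected components of a logical 3D array, plain BFS
connectedComponents26 <- function(support) {
  dims <- dim(support)
  labels <- array(0L, dim = dims)
  nbr <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, ]
  comp <- 0L
  idx <- which(support, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    if (labels[idx[r, 1], idx[r, 2], idx[r, 3]] > 0L) next
    comp <- comp + 1L
    queue <- list(idx[r, ])
    labels[idx[r, 1], idx[r, 2], idx[r, 3]] <- comp
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbr))) {
        w <- v + nbr[k, ]
        if (any(w < 1L) || any(w > dims)) next
        if (support[w[1], w[2], w[3]] &&
            labels[w[1], w[2], w[3]] == 0L) {
          labels[w[1], w[2], w[3]] <- comp
          queue[[length(queue) + 1L]] <- w
        }
      }
    }
  }
  comp
}

# a random phantom selection as 0-based indices
randomSelection <- function(n, size = NULL) {
  if (is.null(size)) size <- sample(0:n, 1L)
  sort(sample(seq_len(n) - 1L, size))
}
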