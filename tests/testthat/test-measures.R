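# overlap and agreement measures, both representations

test_that("the 2x5-grid toy example gives streamline Dice 0 and voxel Dice 0.75", {
  t <- workedExample()
  yellow <- Selection(2L, t)
  green <- Selection(3L, t)
  expect_identical(streamlineDice(yellow, green), 0)
  my <- binaryMask(densityMap(t, yellow, mode = "points"))
  mg <- binaryMask(densityMap(t, green, mode = "points"))
  expect_equal(sum(maskSupport(my)), 5)
  expect_equal(sum(maskSupport(mg)), 3)
  expect_identical(voxelDice(my, mg), 0.75)
  expect_identical(jaccardIndex(my, mg), 0.6)
  # the identical red/blue pair has Dice 1 in both representations
  red <- Selection(0L, t); blue <- Selection(1L, t)
  expect_identical(streamlineDice(red, red), 1)
  expect_identical(voxelDice(binaryMask(densityMap(t, red, mode = "points")),
                             binaryMask(densityMap(t, blue, mode = "points"))),
                   1)
})

test_that("streamline Dice/Jaccard follow the set formulas and conventions", {
  p <- "parent"
  s <- function(i) Selection(as.integer(i), p)
  expect_equal(streamlineDice(s(c(1, 2, 3)), s(c(2, 3, 4))), 2 / 3)
  expect_equal(jaccardIndex(s(c(1, 2, 3)), s(c(2, 3, 4))), 0.5)
  expect_identical(streamlineDice(s(integer(0)), s(integer(0))), 1)
  expect_identical(streamlineDice(s(integer(0)), s(1)), 0)
  expect_error(streamlineDice(s(1), Selection(1L, "other")),
               "different parents")
})

test_that("measures agree with brute-force oracles over a 10-streamline universe", {
  n <- 10L
  subsets <- lapply(0:(2^n - 1), function(bits)
    (which(bitwAnd(bits, 2^(0:(n - 1))) > 0) - 1L))
  sels <- lapply(subsets, Selection, parent = "u10")
  # pair every subset with a deterministic partner sweeping the lattice
  partner <- function(i) bitwXor(i, 341L)  # 0101010101
  for (i in seq_along(subsets)) {
    j <- partner(i - 1L) + 1L
    a <- subsets[[i]]; b <- subsets[[j]]
    expect_equal(streamlineDice(sels[[i]], sels[[j]]), oracleDice(a, b, n),
                 tolerance = 1e-12)
    expect_equal(jaccardIndex(sels[[i]], sels[[j]]), oracleJaccard(a, b, n),
                 tolerance = 1e-12)
    cc <- confusionCounts(sels[[i]], sels[[j]], universe = n)
    want <- oracleSetCounts(a, b, n)
    expect_identical(c(cc@TP, cc@FP, cc@FN, cc@TN),
                     as.numeric(unlist(want)))
  }
})

test_that("Dice-Jaccard identity D = 2J/(1+J) holds on random selections", {
  set.seed(77)
  for (i in 1:50) {
    a <- Selection(randomSelection(40), "p")
    b <- Selection(randomSelection(40), "p")
    d <- streamlineDice(a, b); j <- jaccardIndex(a, b)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
    expect_true(j <= d + 1e-15)
    expect_equal(d, streamlineDice(b, a))
  }
})

test_that("density correlation matches the closed-form Pearson oracle", {
  g <- unitGrid(c(4L, 4L, 4L))
  mk <- function(vals) {
    counts <- array(0L, dim = c(4L, 4L, 4L))
    counts[seq_along(vals)] <- as.integer(vals)
    new("DensityMap", grid = g, counts = counts, nClipped = 0L)
  }
  a <- mk(c(1, 2, 3)); b <- mk(c(3, 2, 1))
  expect_equal(densityCorrelation(a, b), -1, tolerance = 1e-12)
  expect_equal(densityCorrelation(a, a), 1, tolerance = 1e-12)
  a2 <- mk(c(1, 0, 2, 4)); b2 <- mk(c(2, 1, 1, 3))
  expect_equal(densityCorrelation(a2, b2),
               oraclePearson(c(1, 0, 2, 4), c(2, 1, 1, 3)),
               tolerance = 1e-12)
  # zero variance on support is an error, not NaN
  expect_error(densityCorrelation(mk(c(1, 1, 1)), mk(c(1, 2, 3))),
               "zero variance")
  # random maps vs the oracle on the union support
  set.seed(5)
  for (i in 1:20) {
    x <- mk(rpois(30, 1)); y <- mk(rpois(30, 1))
    sel <- mapCounts(x) > 0 | mapCounts(y) > 0
    if (sum(sel) < 2) next
    vx <- as.numeric(mapCounts(x)[sel]); vy <- as.numeric(mapCounts(y)[sel])
    if (sd(vx) == 0 || sd(vy) == 0) next
    expect_equal(densityCorrelation(x, y), oraclePearson(vx, vy),
                 tolerance = 1e-12)
  }
})

test_that("confusion counts and classification metrics follow the formulas", {
  u <- 10L
  gold <- Selection(1:4, "p")
  pred <- Selection(3:6, "p")
  cc <- confusionCounts(pred, gold, universe = u)
  expect_identical(c(cc@TP, cc@FP, cc@FN, cc@TN), c(2, 2, 2, 4))
  # perfect prediction
  m <- classificationMetrics(confusionCounts(gold, gold, universe = u))
  expect_true(all(m[c("sensitivity", "specificity", "precision",
                      "accuracy", "youden", "kappa")] == 1))
  # empty prediction: TP = 0, FN = |gold|
  cc0 <- confusionCounts(Selection(integer(0), "p"), gold, universe = u)
  expect_identical(c(cc0@TP, cc0@FN), c(0, 4))
  m0 <- classificationMetrics(cc0)
  expect_true(is.na(m0["precision"]))
  expect_true("precision" %in% attr(m0, "undefined"))
  # the hand-computed 3/1/1/5 example
  m2 <- classificationMetrics(ConfusionCounts(3, 1, 1, 5))
  expect_equal(unname(m2["accuracy"]), 0.8)
  expect_equal(unname(m2["kappa"]), 0.28 / 0.48, tolerance = 1e-12)
  expect_equal(unname(m2["kappa"]), oracleKappa(3, 1, 1, 5), tolerance = 1e-12)
  expect_equal(unname(m2["youden"]), 3 / 4 + 5 / 6 - 1, tolerance = 1e-12)
})

test_that("kappa approaches Dice as the true-negative count grows", {
  tp <- 30; fp <- 10; fn <- 5
  dice <- 2 * tp / (2 * tp + fp + fn)
  gaps <- vapply(c(1e3, 1e4, 1e5, 1e6), function(tn) {
    k <- unname(classificationMetrics(ConfusionCounts(tp, fp, fn, tn))["kappa"])
    abs(k - dice)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[4], 1e-3)
})

test_that("bundle stats report count, volume, length and scalar means", {
  g <- unitGrid(c(16L, 16L, 16L))
  straight <- cbind(seq(2, 12, length.out = 21), 5, 5)  # arc length 10 mm
  t <- Tractogram(list(straight, cbind(5, seq(2, 7, length.out = 11), 8)), g)
  st <- bundleStats(t, Selection(0L, t))
  expect_equal(st$mean_length_mm, 10)
  expect_equal(st$streamline_count, 1L)
  # volume: support voxels x 1 mm^3, in cm^3
  d <- densityMap(t, Selection(0L, t))
  expect_equal(st$volume_cm3, sum(mapCounts(d) > 0) / 1000)
  # constant scalar map -> mean 0.5 regardless of weighting
  fa <- array(0.5, dim = c(16L, 16L, 16L))
  expect_equal(bundleStats(t, Selection(0L, t), scalarMap = fa)$mean_scalar, 0.5)
  expect_equal(bundleStats(t, Selection(0L, t), scalarMap = fa,
                           weighted = TRUE)$mean_scalar, 0.5)
  # empty selection is flagged, not an error
  st0 <- bundleStats(t, Selection(integer(0), t))
  expect_equal(st0$streamline_count, 0L)
  expect_equal(st0$volume_cm3, 0)
  expect_true(is.na(st0$mean_length_mm))
})
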