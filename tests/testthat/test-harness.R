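# triplication, anonymization, de-randomization, fusion, statistics

test_that("flip is an involution and translation inverts exactly", {
  g <- ReferenceGrid(c(32L, 32L, 32L))  # centered grid
  f <- flipTransform(g)
  expect_equal(f %*% f, diag(4), tolerance = 1e-12)
  tr <- translateTransform(g, c(2L, 3L, 1L))
  expect_equal(solve(tr) %*% tr, diag(4), tolerance = 1e-15)
  # flip about the centered grid's mid-plane is exact negation of x
  pts <- matrix(rnorm(30), ncol = 3)
  flipped <- pts %*% t(f[1:3, 1:3]) + matrix(f[1:3, 4], 10, 3, byrow = TRUE)
  back <- flipped %*% t(f[1:3, 1:3]) + matrix(f[1:3, 4], 10, 3, byrow = TRUE)
  expect_identical(back, pts)
})

test_that("triplication yields 3 named datasets and a bijective manifest", {
  ph <- makePhantom(20, 10, seed = 3)
  trip <- makeTriplicates(ph$tractogram, seed = 5L)
  expect_length(trip$datasets, 3L)
  m <- trip$manifest
  expect_setequal(m$variant, c("original", "flipped", "translated"))
  expect_false(anyDuplicated(m$anonymized_name) > 0)
  expect_identical(sort(names(trip$datasets)), sort(m$anonymized_name))
  expect_setequal(m$order, 1:3)
  # 5 subjects -> 15 anonymized datasets, still a bijection
  phs <- lapply(1:5, function(i) makePhantom(10, 5, seed = 100 + i))
  trips <- lapply(seq_along(phs), function(i)
    makeTriplicates(phs[[i]]$tractogram, seed = 200 + i))
  big <- combineManifests(lapply(trips, `[[`, "manifest"))
  expect_equal(nrow(big), 15L)
  expect_false(anyDuplicated(big$anonymized_name) > 0)
})

test_that("manifests round-trip through CSV + JSON sidecar", {
  ph <- makePhantom(10, 5, seed = 7)
  trip <- makeTriplicates(ph$tractogram, seed = 9L)
  f <- withr::local_tempfile(fileext = ".csv")
  writeStudyManifest(trip$manifest, f)
  back <- readStudyManifest(f)
  expect_identical(back$anonymized_name, trip$manifest$anonymized_name)
  expect_identical(back$variant, trip$manifest$variant)
  tr <- attr(back, "transforms")
  for (nm in names(tr))
    expect_equal(tr[[nm]], attr(trip$manifest, "transforms")[[nm]],
                 tolerance = 1e-15)
})

test_that("a geometric robot rater de-randomizes to the same indices on every variant", {
  # robot rule: keep streamlines of arc length above the median; arc length
  # is invariant to the flip and the translation, so all three variants must
  # de-randomize to the identical index set
  ph <- makePhantom(40, 20, seed = 31)
  parent <- ph$tractogram
  trip <- makeTriplicates(parent, seed = 33L)
  robot <- function(t) {
    len <- vapply(streamlines(t), function(s)
      sum(sqrt(rowSums(diff(s)^2))), numeric(1))
    which(len > median(len)) - 1L
  }
  planted <- robot(parent)
  bundles <- lapply(trip$datasets, function(v)
    Tractogram(streamlines(v, robot(v) + 1L), mapGrid(v)))
  res <- deanonymize(bundles, trip$manifest, parent, rater = "robot")
  subject <- tractId(parent)
  for (variant in c("original", "flipped", "translated"))
    expect_identical(selectionIndices(res$selections[[subject]][[variant]]),
                     as.integer(planted))
  fused <- fuseTriplicates(res, subject)
  expect_identical(selectionIndices(fused), as.integer(planted))
})

test_that("deanonymize reports missing and extra bundles by name", {
  ph <- makePhantom(10, 5, seed = 37)
  trip <- makeTriplicates(ph$tractogram, seed = 39L)
  sel <- Selection(0:3, ph$tractogram)
  bundles <- lapply(trip$datasets, function(v)
    Tractogram(streamlines(v, 1:4), mapGrid(v)))
  broken <- bundles[-1]
  broken[["deadbeef"]] <- bundles[[1]]
  expect_error(deanonymize(broken, trip$manifest, ph$tractogram),
               "missing .*deadbeef|deadbeef")
})

test_that("fusion unions the three replicates; alternatives nest", {
  ph <- makePhantom(20, 0, seed = 41)
  t <- ph$tractogram
  sels <- list(original = Selection(c(1L, 2L), t),
               flipped = Selection(c(2L, 3L), t),
               translated = Selection(c(3L, 4L), t))
  res <- raterResult("r", "expert", setNames(list(sels), tractId(t)))
  fused <- fuseTriplicates(res, tractId(t))
  expect_identical(selectionIndices(fused), 1:4)
  maj <- fuseTriplicates(res, tractId(t), method = "majority")
  expect_identical(selectionIndices(maj), c(2L, 3L))
  inter <- fuseTriplicates(res, tractId(t), method = "intersection")
  expect_length(selectionIndices(inter), 0L)
  # |fused| >= max per-replicate size
  expect_gte(selectionSize(fused),
             max(vapply(sels, selectionSize, integer(1))))
  # identical replicates fuse to themselves
  same <- raterResult("r", "expert",
                      setNames(list(list(original = sels$original,
                                         flipped = sels$original,
                                         translated = sels$original)),
                               tractId(t)))
  expect_identical(selectionIndices(fuseTriplicates(same, tractId(t))),
                   selectionIndices(sels$original))
  # incomplete triplicates are an error
  miss <- raterResult("r", "expert",
                      setNames(list(sels[1:2]), tractId(t)))
  expect_error(fuseTriplicates(miss, tractId(t)), "missing variants")
})

test_that("intra scoring emits 3 pairs per subject and 15 values for 5 subjects", {
  st <- simulateStudy(nSubjects = 5, nExperts = 1, nNonexperts = 1,
                      nCore = 30, nDistractor = 10, seed = 51)
  res <- deanonymize(st$bundles[[1]], st$manifest, st$parents,
                     rater = st$raters$rater[1], group = st$raters$group[1])
  tab <- intraRaterScores(res, st$parents, measures = "dice_streamlines")
  expect_equal(nrow(tab), 15L)
  expect_true(all(tab$comparison == "intra"))
  expect_equal(length(unique(tab$subject)), 5L)
  # a rater identical across replicates scores intra Dice 1 everywhere
  t <- st$parents[[1]]
  sel <- Selection(0:9, t)
  same <- raterResult("c", "expert",
                      setNames(list(list(original = sel, flipped = sel,
                                         translated = sel)), tractId(t)))
  tab1 <- intraRaterScores(same, st$parents,
                           measures = c("dice_streamlines", "dice_voxels"))
  expect_true(all(tab1$value == 1))
})

test_that("inter scoring covers all rater pairs on all subjects", {
  st <- simulateStudy(nSubjects = 2, nExperts = 2, nNonexperts = 1,
                      nCore = 30, nDistractor = 10, seed = 53)
  out <- runStudy(st, measures = "dice_streamlines")
  inter <- out$scores[out$scores$comparison == "inter", ]
  # 3 raters -> 3 unordered pairs, 2 rows each, 2 subjects
  expect_equal(nrow(inter), 3 * 2 * 2)
  # the table is symmetric: each pair appears once per orientation
  expect_equal(sum(inter$rater == st$raters$rater[1]), 4)
  # identical raters agree perfectly
  t <- st$parents[[1]]
  sel <- Selection(0:9, t)
  mk <- function(nm) raterResult(nm, "expert",
    setNames(list(list(original = sel, flipped = sel, translated = sel)),
             tractId(t)))
  tab <- interRaterScores(list(mk("a"), mk("b")), st$parents[1],
                          measures = "dice_streamlines")
  expect_true(all(tab$value == 1))
  expect_error(interRaterScores(list(mk("a")), st$parents[1]),
               "at least 2")
})

test_that("gold scoring separates over- and under-segmentation signatures", {
  ph <- makePhantom(30, 10, seed = 57)
  t <- ph$tractogram
  gold <- buildGoldStandard(list(Selection(0:19, t)), t, 1L)
  mkres <- function(nm, idx) raterResult(nm, "expert",
    setNames(list(list(original = Selection(idx, t),
                       flipped = Selection(idx, t),
                       translated = Selection(idx, t))), tractId(t)))
  golds <- setNames(list(gold), tractId(t))
  # pred strictly contains gold: sensitivity 1, precision < 1
  over <- goldScores(list(mkres("over", 0:24)), golds, t,
                     measures = "dice_streamlines")
  sens <- over$value[over$measure == "sensitivity_streamlines"]
  prec <- over$value[over$measure == "precision_streamlines"]
  expect_equal(sens, 1)
  expect_lt(prec, 1)
  # pred strictly inside gold: precision 1, sensitivity < 1
  under <- goldScores(list(mkres("under", 0:14)), golds, t,
                      measures = "dice_streamlines")
  expect_equal(under$value[under$measure == "precision_streamlines"], 1)
  expect_lt(under$value[under$measure == "sensitivity_streamlines"], 1)
  # pred equal to gold: Dice and kappa 1
  eq <- goldScores(list(mkres("eq", 0:19)), golds, t,
                   measures = "dice_streamlines")
  expect_equal(eq$value[eq$measure == "dice_streamlines"], 1)
  expect_equal(eq$value[eq$measure == "kappa_streamlines"], 1)
})

test_that("median/IQR use linear-interpolation quartiles", {
  expect_equal(summarizeScores(1:5), list(median = 3, iqr = 2, n = 5L))
  expect_equal(summarizeScores(rep(7, 10))$iqr, 0)
  set.seed(61)
  for (i in 1:20) {
    x <- rnorm(sample(3:40, 1))
    s <- summarizeScores(x)
    expect_equal(s$median, oracleQuantile(x, 0.5), tolerance = 1e-12)
    expect_equal(s$iqr, oracleQuantile(x, 0.75) - oracleQuantile(x, 0.25),
                 tolerance = 1e-12)
  }
  expect_error(summarizeScores(numeric(0)), "no values")
})

test_that("Mann-Whitney U matches brute-force pair counting and wilcox.test", {
  set.seed(63)
  for (i in 1:20) {
    a <- sample(0:5, sample(2:8, 1), replace = TRUE) / 2
    b <- sample(0:5, sample(2:8, 1), replace = TRUE) / 2
    got <- groupCompare(a, b)
    expect_equal(got$U, oracleU(a, b))
    expect_gte(got$p.value, 0)
    expect_lte(got$p.value, 1)
  }
  # identical samples: exact enumeration gives p = 1
  expect_equal(groupCompare(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  # large samples: normal approximation agrees with wilcox.test
  set.seed(65)
  a <- rnorm(40); b <- rnorm(45, 0.5)
  got <- groupCompare(a, b)
  want <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(got$U, unname(want$statistic))
  expect_equal(got$p.value, want$p.value, tolerance = 1e-10)
  # shifted distributions separate decisively
  set.seed(67)
  x <- rnorm(50); y <- rnorm(50, 3)
  expect_lt(groupCompare(x, y)$p.value, 0.01)
  # degenerate all-tie case is flagged
  expect_true(groupCompare(rep(1, 5), rep(1, 6))$degenerate)
})

test_that("rater score correlation follows the Pearson formula", {
  intra <- c(a = 0.5, b = 0.7, c = 0.9, d = 0.6)
  expect_equal(raterScoreCorrelation(intra, intra), 1)
  expect_equal(raterScoreCorrelation(intra, -intra + 1), -1)
  set.seed(69)
  x <- rnorm(8); y <- rnorm(8)
  names(x) <- names(y) <- letters[1:8]
  expect_equal(raterScoreCorrelation(x, y), oraclePearson(x, y),
               tolerance = 1e-12)
  expect_warning(r <- raterScoreCorrelation(rep(1, 4), rnorm(4)),
                 "constant")
  expect_true(is.na(r))
  expect_error(raterScoreCorrelation(1:2, 1:2), "at least 3")
})

test_that("score tables are invariant to anonymized-name permutation", {
  st <- simulateStudy(nSubjects = 2, nExperts = 2, nNonexperts = 0,
                      nCore = 25, nDistractor = 10, seed = 71)
  res1 <- deanonymize(st$bundles[[1]], st$manifest, st$parents, rater = "r1")
  perm <- sample(names(st$bundles[[1]]))
  res2 <- deanonymize(st$bundles[[1]][perm], st$manifest, st$parents,
                      rater = "r1")
  t1 <- intraRaterScores(res1, st$parents, measures = "dice_streamlines")
  t2 <- intraRaterScores(res2, st$parents, measures = "dice_streamlines")
  expect_equal(t1$value, t2$value)
})
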