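# TRK/TCK round trips and bundle-to-index resolution

test_that("empty and tiny tractograms survive write/read in both formats", {
  g <- unitGrid(c(20L, 20L, 20L))
  empty <- Tractogram(list(), g, id = "empty")
  one <- Tractogram(list(rbind(c(1.5, 2.5, 3.5), c(4.5, 5.5, 6.5))), g)
  for (fmt in c("trk", "tck")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    writeTractogram(empty, f)
    expect_equal(nStreamlines(readTractogram(f, grid = g)), 0L)
    writeTractogram(one, f)
    back <- readTractogram(f, grid = g)
    expect_equal(nStreamlines(back), 1L)
    expect_equal(nrow(streamlines(back)[[1]]), 2L)
  }
})

test_that("write/read round-trips a 150-streamline phantom within 1e-4 mm", {
  ph <- makePhantom(100, 50, seed = 11)
  t <- ph$tractogram
  maxdiff <- function(a, b)
    max(mapply(function(x, y) max(abs(x - y)), streamlines(a), streamlines(b)))
  for (fmt in c("trk", "tck")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    writeTractogram(t, f)
    back <- readTractogram(f, grid = mapGrid(t))
    expect_equal(nStreamlines(back), 150L)
    expect_identical(vapply(streamlines(back), nrow, integer(1)),
                     vapply(streamlines(t), nrow, integer(1)))
    expect_lt(maxdiff(t, back), 1e-4)
  }
})

test_that("TRK and TCK written from the same phantom agree in world mm", {
  t <- makePhantom(40, 10, seed = 5)$tractogram
  ftrk <- withr::local_tempfile(fileext = ".trk")
  ftck <- withr::local_tempfile(fileext = ".tck")
  writeTractogram(t, ftrk)
  writeTractogram(t, ftck)
  a <- readTractogram(ftrk, grid = mapGrid(t))
  b <- readTractogram(ftck, grid = mapGrid(t))
  d <- max(mapply(function(x, y) max(abs(x - y)),
                  streamlines(a), streamlines(b)))
  expect_lt(d, 1e-3)
})

test_that("reading rejects corrupt files, bad extensions and grid mismatch", {
  f <- withr::local_tempfile(fileext = ".trk")
  writeBin(charToRaw("not a tractogram at all"), f)
  expect_error(readTractogram(f), "not a TRK")
  expect_error(readTractogram(withr::local_tempfile(fileext = ".xyz")),
               "no such file")
  t <- makePhantom(5, 0, seed = 1)$tractogram
  writeTractogram(t, f)
  other <- ReferenceGrid(c(64L, 64L, 64L))
  expect_error(readTractogram(f, grid = other), "does not match")
  ftck <- withr::local_tempfile(fileext = ".tck")
  writeTractogram(t, ftck)
  expect_error(readTractogram(ftck), "ReferenceGrid")
})

test_that("resolveSelection recovers written selections through files", {
  ph <- makePhantom(60, 20, seed = 2)
  t <- ph$tractogram
  idx <- c(2L, 5L, 9L)
  b <- Tractogram(streamlines(t, idx + 1L), mapGrid(t))
  f <- withr::local_tempfile(fileext = ".trk")
  writeTractogram(b, f)
  sel <- resolveSelection(t, readTractogram(f, grid = mapGrid(t)))
  expect_identical(selectionIndices(sel), idx)
})

test_that("unmatched bundle streamlines raise a resolution error with a count", {
  t <- makePhantom(10, 0, seed = 3)$tractogram
  alien <- Tractogram(list(rbind(c(100, 100, 100), c(101, 101, 101))),
                      mapGrid(t))
  expect_error(resolveSelection(t, alien), "1 bundle streamline")
})

test_that("duplicate geometry claims the lowest parent indices first", {
  g <- unitGrid()
  s <- rbind(c(1, 1, 1), c(2, 2, 2))
  other <- rbind(c(5, 5, 5), c(6, 6, 6))
  parent <- Tractogram(list(s, other, s, s), g, id = "dup")
  # bundle contains the duplicated geometry twice
  bundle <- Tractogram(list(s, s), g)
  sel <- resolveSelection(parent, bundle)
  expect_identical(selectionIndices(sel), c(0L, 2L))
  # three copies claim all three parent slots
  sel3 <- resolveSelection(parent, Tractogram(list(s, s, s), g))
  expect_identical(selectionIndices(sel3), c(0L, 2L, 3L))
  # four copies cannot be matched
  expect_error(resolveSelection(parent, Tractogram(list(s, s, s, s), g)),
               "could not be matched")
})

test_that("round-trip write/read/resolve recovers random selections exactly", {
  ph <- makePhantom(80, 40, seed = 8)
  t <- ph$tractogram
  g <- mapGrid(t)
  set.seed(99)
  for (case in 1:100) {
    idx <- randomSelection(120)
    fmt <- if (case %% 2 == 0) ".trk" else ".tck"
    f <- withr::local_tempfile(fileext = fmt)
    if (length(idx) == 0L) next
    writeTractogram(Tractogram(streamlines(t, idx + 1L), g), f)
    sel <- resolveSelection(t, readTractogram(f, grid = g))
    expect_identical(selectionIndices(sel), idx)
  }
})

test_that("resolution is invariant to bundle file order", {
  t <- makePhantom(40, 0, seed = 4)$tractogram
  idx <- c(0L, 3L, 7L, 21L, 33L)
  g <- mapGrid(t)
  shuffled <- Tractogram(streamlines(t, idx + 1L)[c(3, 1, 5, 2, 4)], g)
  plain <- Tractogram(streamlines(t, idx + 1L), g)
  expect_identical(selectionIndices(resolveSelection(t, shuffled)),
                   selectionIndices(resolveSelection(t, plain)))
})
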