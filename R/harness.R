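# Blinded triplication study machinery: every subject's tractogram is
# presented three times (untouched, mirrored in X, rigidly translated) under
# random names, so raters cannot tell they are repeating a task. After
# collection the manifest de-randomizes everything back onto the original
# parent, replicates are fused, and intra-/inter-/gold agreement scores are
# tabulated.

VARIANTS <- c("original", "flipped", "translated")

## ---------------------------------------------------------------------------
## transforms
## ---------------------------------------------------------------------------

#' World-space transforms of the triplication design
#'
#' `flipTransform` mirrors about the grid's mid-X plane (voxel index
#' `i -> Nx - 1 - i`, expressed as an exact world-space affine);
#' `translateTransform` shifts by a whole number of voxels. Both are exactly
#' invertible: the flip is an involution and the translation inverse is the
#' opposite shift.
#'
#' @param grid a [ReferenceGrid-class].
#' @param voxels integer(3) translation in voxels.
#' @return A 4x4 world-mm affine.
#' @export
flipTransform <- function(grid) {
  stopifnot(is(grid, "ReferenceGrid"))
  fv <- diag(4)
  fv[1, 1] <- -1
  fv[1, 4] <- grid@shape[1] - 1
  grid@affine %*% fv %*% solve(grid@affine)
}

#' @rdname flipTransform
#' @export
translateTransform <- function(grid, voxels) {
  stopifnot(is(grid, "ReferenceGrid"), length(voxels) == 3L)
  m <- diag(4)
  m[1:3, 4] <- grid@affine[1:3, 1:3] %*% as.numeric(voxels)
  m
}

#' Apply a world-space affine to a whole tractogram
#'
#' Streamline order and point counts are preserved, so selections by index
#' are unaffected by the transform.
#'
#' @param t a [Tractogram-class].
#' @param m a 4x4 affine in world mm.
#' @param id label for the transformed tractogram (default: keep `t`'s).
#' @return A transformed [Tractogram-class] on the same grid.
#' @export
transformTractogram <- function(t, m, id = NULL) {
  stopifnot(is(t, "Tractogram"), identical(dim(m), c(4L, 4L)))
  Tractogram(lapply(t@streamlines, function(s) applyAffine(m, s)),
             t@grid, id = if (is.null(id)) t@id else id)
}

## ---------------------------------------------------------------------------
## triplication + manifest
## ---------------------------------------------------------------------------

#' Triplicate a subject's tractogram for a blinded study
#'
#' Produces the three datasets a rater receives for one subject — the
#' original, an X-flipped copy, and a copy translated by whole voxels —
#' under seeded pseudo-anonymous names, together with the manifest needed to
#' de-randomize the returned segmentations.
#'
#' @param parent the subject's [Tractogram-class].
#' @param translation integer(3) rigid shift in voxels for the translated
#'   variant; keep it small enough that the bundle region stays in-grid.
#' @param seed integer seed for the anonymized names and task order.
#' @return A list with `datasets` (named list of three [Tractogram-class]
#'   objects keyed by anonymized name) and `manifest` (a `StudyManifest`
#'   data frame with columns `anonymized_name`, `subject`, `variant`, `tx`,
#'   `ty`, `tz`, `order`, and the per-dataset 4x4 world transforms in
#'   `attr(, "transforms")`).
#' @export
makeTriplicates <- function(parent, translation = c(2L, 3L, 1L), seed = 1L) {
  stopifnot(is(parent, "Tractogram"))
  translation <- as.integer(translation)
  grid <- parent@grid
  transforms <- list(
    original = diag(4),
    flipped = flipTransform(grid),
    translated = translateTransform(grid, translation))
  drawn <- withSeed(seed, list(names = anonNames(3L),
                               order = sample.int(3L)))
  datasets <- setNames(vector("list", 3L), drawn$names)
  for (i in seq_along(VARIANTS))
    datasets[[i]] <- transformTractogram(parent, transforms[[i]],
                                         id = drawn$names[i])
  manifest <- data.frame(
    anonymized_name = drawn$names,
    subject = tractId(parent),
    variant = VARIANTS,
    tx = c(0L, 0L, translation[1]),
    ty = c(0L, 0L, translation[2]),
    tz = c(0L, 0L, translation[3]),
    order = drawn$order,
    stringsAsFactors = FALSE)
  attr(manifest, "transforms") <- setNames(transforms, drawn$names)
  attr(manifest, "seed") <- seed
  class(manifest) <- c("StudyManifest", "data.frame")
  list(datasets = datasets, manifest = manifest)
}

#' Combine per-subject manifests into one study manifest
#'
#' @param ... `StudyManifest` data frames from [makeTriplicates()].
#' @return A single `StudyManifest` covering all subjects; anonymized names
#'   must be unique across subjects.
#' @export
combineManifests <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !is.data.frame(parts[[1]])) parts <- parts[[1]]
  out <- do.call(rbind, lapply(parts, function(m) {
    stopifnot(is.data.frame(m))
    as.data.frame(m)
  }))
  rownames(out) <- NULL
  if (anyDuplicated(out$anonymized_name))
    stop("anonymized names collide across subjects; use different seeds")
  tr <- do.call(c, lapply(parts, attr, "transforms"))
  attr(out, "transforms") <- tr
  class(out) <- c("StudyManifest", "data.frame")
  out
}

#' Write / read a study manifest
#'
#' The manifest table goes to CSV; the exact 4x4 world transforms go to a
#' JSON sidecar (`<path>.transforms.json`) so de-randomization is
#' reproducible bit-for-bit.
#'
#' @param manifest a `StudyManifest` from [makeTriplicates()] /
#'   [combineManifests()].
#' @param path CSV path.
#' @return `path` (write) or the manifest (read).
#' @export
writeStudyManifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  tr <- attr(manifest, "transforms")
  jsonlite::write_json(lapply(tr, function(m) unclass(m)),
                       paste0(path, ".transforms.json"),
                       digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeStudyManifest
#' @export
readStudyManifest <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".transforms.json")
  if (file.exists(side)) {
    tr <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(out, "transforms") <- lapply(tr, function(m) matrix(m, 4L, 4L))
  }
  class(out) <- c("StudyManifest", "data.frame")
  out
}

## ---------------------------------------------------------------------------
## de-randomization
## ---------------------------------------------------------------------------

#' A rater's de-randomized study result
#'
#' @param rater rater identifier.
#' @param group `"expert"` or `"nonexpert"`.
#' @param selections nested list: `selections[[subject]][[variant]]` is a
#'   [Selection-class] on that subject's original parent.
#' @param meta optional data frame of task metadata (date, start time,
#'   duration, ...).
#' @return A `RaterResult` (S3 list).
#' @export
raterResult <- function(rater, group = c("expert", "nonexpert"),
                        selections, meta = NULL) {
  group <- match.arg(group)
  structure(list(rater = rater, group = group, selections = selections,
                 meta = meta),
            class = "RaterResult")
}

#' @export
print.RaterResult <- function(x, ...) {
  cat(sprintf("RaterResult '%s' (%s): %d subject(s) x %s\n", x$rater,
              x$group, length(x$selections),
              paste(names(x$selections[[1]]), collapse = "/")))
  invisible(x)
}

#' De-randomize a rater's returned bundles
#'
#' Maps each anonymously-named bundle back to its (subject, variant) pair
#' via the manifest and resolves it to streamline indices of the subject's
#' *original* parent. Resolution happens in the variant's own space, against
#' the forward-transformed parent: triplication preserves streamline order,
#' so variant indices and original indices coincide and no floating-point
#' inverse transform can disturb the identity.
#'
#' @param bundles named list of [Tractogram-class] bundles (or file paths),
#'   keyed by anonymized dataset name.
#' @param manifest the `StudyManifest`.
#' @param parents named list of original parent [Tractogram-class] objects,
#'   keyed by subject id (or a single `Tractogram` for one-subject studies).
#' @param rater,group passed to [raterResult()].
#' @param tol resolution tolerance in mm (see [resolveSelection()]).
#' @return A `RaterResult`.
#' @export
deanonymize <- function(bundles, manifest, parents, rater = "rater",
                        group = "expert", tol = 1e-3) {
  stopifnot(is.data.frame(manifest))
  if (is(parents, "Tractogram"))
    parents <- setNames(list(parents), tractId(parents))
  missing <- setdiff(manifest$anonymized_name, names(bundles))
  extra <- setdiff(names(bundles), manifest$anonymized_name)
  if (length(missing) || length(extra))
    stop(sprintf(
      "bundle/manifest mismatch: missing [%s], unexpected [%s]",
      paste(missing, collapse = ", "), paste(extra, collapse = ", ")))
  transforms <- attr(manifest, "transforms")
  selections <- list()
  for (r in seq_len(nrow(manifest))) {
    name <- manifest$anonymized_name[r]
    subject <- manifest$subject[r]
    variant <- manifest$variant[r]
    parent <- parents[[subject]]
    if (is.null(parent))
      stop(sprintf("no parent tractogram supplied for subject '%s'", subject))
    b <- bundles[[name]]
    if (is.character(b)) b <- readTractogram(b, grid = parent@grid)
    variantParent <- transformTractogram(parent, transforms[[name]], id = name)
    sel <- resolveSelection(variantParent, b, tol = tol)
    selections[[subject]][[variant]] <- Selection(sel@indices, parent)
  }
  raterResult(rater, group, selections)
}

#' Fuse a rater's triplicate selections into one bundle
#'
#' The three de-randomized replicates of a subject are fused into a single
#' selection before inter-rater and gold-standard comparison, to keep a
#' rater's own replicate-to-replicate variability out of those scores. The
#' default fusion is the union of the three index sets; `"majority"` keeps
#' streamlines picked in at least 2 of 3 replicates, `"intersection"` those
#' picked in all 3.
#'
#' @param result a `RaterResult`.
#' @param subject subject id.
#' @param method `"union"` (default), `"majority"` or `"intersection"`.
#' @return A [Selection-class].
#' @export
fuseTriplicates <- function(result, subject,
                            method = c("union", "majority", "intersection")) {
  method <- match.arg(method)
  sels <- result$selections[[subject]]
  if (is.null(sels) || !all(VARIANTS %in% names(sels)))
    stop(sprintf("subject '%s' is missing variants: %s", subject,
                 paste(setdiff(VARIANTS, names(sels)), collapse = ", ")))
  sels <- sels[VARIANTS]
  pid <- sels[[1]]@parentId
  idx <- lapply(sels, selectionIndices)
  counts <- table(unlist(idx))
  k <- switch(method, union = 1L, majority = 2L, intersection = 3L)
  Selection(as.integer(names(counts))[counts >= k], pid)
}

## ---------------------------------------------------------------------------
## scoring
## ---------------------------------------------------------------------------

PAIR_MEASURES <- c("dice_streamlines", "jaccard_streamlines",
                   "dice_voxels", "jaccard_voxels", "density_correlation")

# score one pair given cached density maps
scorePair <- function(selA, selB, mapA, mapB, measures) {
  vapply(measures, function(m) switch(m,
    dice_streamlines = streamlineDice(selA, selB),
    jaccard_streamlines = jaccardIndex(selA, selB),
    dice_voxels = voxelDice(mapA, mapB),
    jaccard_voxels = jaccardIndex(binaryMask(mapA), binaryMask(mapB)),
    density_correlation = tryCatch(densityCorrelation(mapA, mapB),
                                   error = function(e) NA_real_),
    stop(sprintf("unknown measure '%s'", m))), numeric(1))
}

scoreRow <- function(rater, group, subject, comparison, other, measure,
                     value) {
  data.frame(rater = rater, group = group, subject = subject,
             hemisphere = "pooled", comparison = comparison, other = other,
             measure = measure, value = as.numeric(value),
             stringsAsFactors = FALSE)
}

#' Intra-rater reproducibility scores
#'
#' Scores all 3 unordered replicate pairs of every subject with every
#' requested measure: with 5 subjects that is the classic 15 values per
#' rater per measure, whose mean is the rater's intra-rater reproducibility
#' score.
#'
#' @param result a `RaterResult` with complete triplicates.
#' @param parents named list of parent [Tractogram-class] objects by subject.
#' @param measures character vector of pairwise measures
#'   (subset of `dice_streamlines`, `jaccard_streamlines`, `dice_voxels`,
#'   `jaccard_voxels`, `density_correlation`).
#' @param mode voxelization mode.
#' @return A long-format `ScoreTable` data frame with columns `rater`,
#'   `group`, `subject`, `hemisphere`, `comparison`, `other`, `measure`,
#'   `value`.
#' @export
intraRaterScores <- function(result, parents,
                             measures = c("dice_streamlines", "dice_voxels",
                                          "density_correlation"),
                             mode = "segments") {
  if (is(parents, "Tractogram"))
    parents <- setNames(list(parents), tractId(parents))
  needVoxel <- any(measures %in% c("dice_voxels", "jaccard_voxels",
                                   "density_correlation"))
  rows <- list()
  for (subject in names(result$selections)) {
    sels <- result$selections[[subject]][VARIANTS]
    if (any(vapply(sels, is.null, logical(1))))
      stop(sprintf("subject '%s' has incomplete triplicates", subject))
    maps <- if (needVoxel)
      lapply(sels, function(s) densityMap(parents[[subject]], s, mode = mode))
    else vector("list", 3L)
    for (pair in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
      vals <- scorePair(sels[[pair[1]]], sels[[pair[2]]],
                        maps[[pair[1]]], maps[[pair[2]]], measures)
      rows[[length(rows) + 1L]] <- scoreRow(
        result$rater, result$group, subject, "intra",
        paste(VARIANTS[pair], collapse = "-"), measures, vals)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ScoreTable", "data.frame")
  out
}

# fused selections and maps for a list of RaterResults, cached once
fusedBundles <- function(results, parents, fusion, mode, needVoxel) {
  lapply(results, function(res) {
    lapply(setNames(nm = names(res$selections)), function(subject) {
      sel <- fuseTriplicates(res, subject, method = fusion)
      list(sel = sel,
           map = if (needVoxel)
             densityMap(parents[[subject]], sel, mode = mode))
    })
  })
}

#' Inter-rater reproducibility scores
#'
#' Fuses each rater's triplicates (see [fuseTriplicates()]) and scores every
#' unordered rater pair on every subject. A rater's inter-rater
#' reproducibility score is the mean of its comparisons with all other
#' raters; both orientations of each pair are therefore emitted (same
#' value, one row per rater of the pair).
#'
#' @param results list of `RaterResult` objects (>= 2).
#' @param parents named list of parent [Tractogram-class] objects by subject.
#' @param measures,mode as in [intraRaterScores()].
#' @param fusion triplicate fusion method.
#' @return A `ScoreTable` data frame.
#' @export
interRaterScores <- function(results, parents,
                             measures = c("dice_streamlines", "dice_voxels",
                                          "density_correlation"),
                             mode = "segments", fusion = "union") {
  if (length(results) < 2L) stop("inter-rater scoring needs at least 2 raters")
  if (is(parents, "Tractogram"))
    parents <- setNames(list(parents), tractId(parents))
  needVoxel <- any(measures %in% c("dice_voxels", "jaccard_voxels",
                                   "density_correlation"))
  fused <- fusedBundles(results, parents, fusion, mode, needVoxel)
  rows <- list()
  for (i in seq_along(results)) for (j in seq_along(results)) {
    if (i >= j) next
    for (subject in names(results[[i]]$selections)) {
      a <- fused[[i]][[subject]]; b <- fused[[j]][[subject]]
      vals <- scorePair(a$sel, b$sel, a$map, b$map, measures)
      ri <- results[[i]]; rj <- results[[j]]
      rows[[length(rows) + 1L]] <- scoreRow(
        ri$rater, ri$group, subject, "inter", rj$rater, measures, vals)
      rows[[length(rows) + 1L]] <- scoreRow(
        rj$rater, rj$group, subject, "inter", ri$rater, measures, vals)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ScoreTable", "data.frame")
  out
}

#' Scores against the per-subject average segmentation
#'
#' Compares each rater's fused bundle with the vote-thresholded average
#' segmentation ("gold standard") of every subject, with the pairwise
#' overlap measures and the confusion-based classification metrics in both
#' representations. The confusion universes are the whole parent tractogram
#' (streamlines) and the whole grid (voxels).
#'
#' @param results list of `RaterResult` objects.
#' @param golds named list by subject, each as returned by
#'   [buildGoldStandard()].
#' @param parents named list of parent [Tractogram-class] objects by subject.
#' @param measures pairwise measures, as in [intraRaterScores()].
#' @param classification also emit sensitivity/specificity/precision/
#'   accuracy/youden/kappa rows per representation.
#' @param mode,fusion as in [interRaterScores()].
#' @return A `ScoreTable` data frame (`comparison == "gold"`).
#' @export
goldScores <- function(results, golds, parents,
                       measures = c("dice_streamlines", "dice_voxels",
                                    "density_correlation"),
                       classification = TRUE,
                       mode = "segments", fusion = "union") {
  if (is(parents, "Tractogram"))
    parents <- setNames(list(parents), tractId(parents))
  fused <- fusedBundles(results, parents, fusion, mode, TRUE)
  goldMaps <- lapply(setNames(nm = names(golds)), function(subject) {
    sel <- golds[[subject]]$streamline
    list(sel = sel,
         map = densityMap(parents[[subject]], sel, mode = mode),
         mask = golds[[subject]]$voxel)
  })
  rows <- list()
  for (i in seq_along(results)) {
    res <- results[[i]]
    for (subject in names(res$selections)) {
      g <- goldMaps[[subject]]
      if (is.null(g)) stop(sprintf("no gold standard for subject '%s'", subject))
      a <- fused[[i]][[subject]]
      vals <- scorePair(a$sel, g$sel, a$map, g$map, measures)
      rows[[length(rows) + 1L]] <- scoreRow(
        res$rater, res$group, subject, "gold", "gold", measures, vals)
      if (classification) {
        cs <- classificationMetrics(confusionCounts(
          a$sel, g$sel, universe = parents[[subject]]))
        cv <- classificationMetrics(confusionCounts(
          binaryMask(a$map), g$mask, universe = "grid"))
        rows[[length(rows) + 1L]] <- scoreRow(
          res$rater, res$group, subject, "gold", "gold",
          paste0(names(cs), "_streamlines"), cs)
        rows[[length(rows) + 1L]] <- scoreRow(
          res$rater, res$group, subject, "gold", "gold",
          paste0(names(cv), "_voxels"), cv)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ScoreTable", "data.frame")
  out
}

## ---------------------------------------------------------------------------
## statistics
## ---------------------------------------------------------------------------

#' Median and interquartile range
#'
#' The reporting convention for all score distributions: median (Q2) and
#' IQR (Q3 - Q1), with quartiles by linear interpolation between order
#' statistics (`stats::quantile` type 7).
#'
#' @param values numeric vector (NAs dropped).
#' @return list with `median`, `iqr`, `n`.
#' @export
summarizeScores <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to summarize")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], iqr = q[3] - q[1], n = length(values))
}

#' Mann-Whitney two-sample comparison
#'
#' Two-sided Mann-Whitney U test for two independent samples, the
#' group-comparison test used for all expert-vs-nonexpert contrasts.
#' For small samples (both sizes <= `exactMax`) the null distribution of U
#' is enumerated over all group assignments of the pooled values, which
#' handles ties exactly; larger samples use the normal approximation with
#' the tie-corrected variance. U counts concordant pairs, ties as 1/2.
#'
#' @param a,b numeric samples.
#' @param exactMax enumerate exactly when both sample sizes are at most
#'   this (default 8).
#' @return list with `U`, `p.value`, `method`, and `degenerate = TRUE` when
#'   all pooled values tie (p is 1 by convention there).
#' @export
groupCompare <- function(a, b, exactMax = 8L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b)
  U <- sum(vapply(a, function(x) sum(x > b) + 0.5 * sum(x == b), numeric(1)))
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L)
    return(list(U = U, p.value = 1, method = "degenerate", degenerate = TRUE))
  if (n1 <= exactMax && n2 <= exactMax) {
    idx <- combn(n1 + n2, n1)
    us <- apply(idx, 2L, function(ii) {
      x <- pooled[ii]; y <- pooled[-ii]
      sum(vapply(x, function(v) sum(v > y) + 0.5 * sum(v == y), numeric(1)))
    })
    mu <- n1 * n2 / 2
    p <- min(1, 2 * min(mean(us <= U), mean(us >= U)))
    return(list(U = U, p.value = p, method = "exact enumeration",
                degenerate = FALSE))
  }
  N <- n1 + n2
  ties <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  list(U = U, p.value = 2 * pnorm(-abs(z)),
       method = "normal approximation (tie-corrected)", degenerate = FALSE)
}

#' Per-rater reproducibility scores and their correlation
#'
#' `raterScore` averages a rater's score-table values per measure — the
#' single "reproducibility score" per rater. `raterScoreCorrelation` is the
#' Pearson correlation between per-rater intra and inter scores, measuring
#' whether raters who agree with themselves also agree with others.
#'
#' @param scores a `ScoreTable` data frame.
#' @param measure measure name to average.
#' @return `raterScore`: named numeric vector of per-rater means.
#' @export
raterScore <- function(scores, measure) {
  sub <- scores[scores$measure == measure, ]
  if (!nrow(sub)) stop(sprintf("no rows for measure '%s'", measure))
  tapply(sub$value, sub$rater, mean, na.rm = TRUE)
}

#' @rdname raterScore
#' @param intra,inter per-rater score vectors (aligned by name when named).
#' @return `raterScoreCorrelation`: Pearson r (`NA` with a warning if a
#'   vector is constant).
#' @export
raterScoreCorrelation <- function(intra, inter) {
  if (!is.null(names(intra)) && !is.null(names(inter))) {
    common <- intersect(names(intra), names(inter))
    intra <- intra[common]; inter <- inter[common]
  }
  if (length(intra) < 3L) stop("need at least 3 raters to correlate scores")
  if (stats::sd(intra) == 0 || stats::sd(inter) == 0) {
    warning("score correlation undefined: a score vector is constant")
    return(NA_real_)
  }
  cor(intra, inter)
}

#' Summarize a study's score table
#'
#' Per (comparison, measure): median/IQR/n per group, plus the two-sided
#' Mann-Whitney p-value between the expert and nonexpert distributions when
#' both are present.
#'
#' @param scores a `ScoreTable` (rows from the scoring functions, rbind-ed).
#' @param alpha significance threshold recorded alongside each p-value
#'   (default 0.01).
#' @return A data frame with one row per comparison x measure x group and
#'   columns `median`, `iqr`, `n`, `p_value`, `significant`.
#' @export
studySummary <- function(scores, alpha = 0.01) {
  out <- list()
  for (comp in unique(scores$comparison)) {
    sub <- scores[scores$comparison == comp, ]
    for (m in unique(sub$measure)) {
      ms <- sub[sub$measure == m, ]
      groups <- split(ms$value, ms$group)
      p <- if (length(groups) == 2L)
        groupCompare(groups[[1]], groups[[2]])$p.value else NA_real_
      for (g in names(groups)) {
        s <- summarizeScores(groups[[g]])
        out[[length(out) + 1L]] <- data.frame(
          comparison = comp, measure = m, group = g,
          median = s$median, iqr = s$iqr, n = s$n,
          p_value = p, significant = !is.na(p) && p < alpha,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
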