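# Synthetic phantom tractograms and simulated raters.
#
# The phantom stands in for a hemisphere tractogram containing one coherent
# bundle: a vertically oriented, gently curving fan of "core" streamlines
# jittered around a common centerline tube, plus off-bundle "distractor"
# clutter. Simulated raters select streamlines with independent Bernoulli
# errors: each core streamline is kept with probability p, each distractor
# picked up with probability q — which gives closed-form expectations for
# the agreement measures (pairwise streamline Dice between two independent
# raters at q = 0 has expectation p).

#' Rater reliability model
#'
#' @param keepProb probability a true-bundle (core) streamline is selected.
#' @param spuriousProb probability an off-bundle (distractor) streamline is
#'   selected.
#' @return A `RaterModel` (S3 list).
#' @export
raterModel <- function(keepProb, spuriousProb = 0) {
  stopifnot(keepProb >= 0, keepProb <= 1,
            spuriousProb >= 0, spuriousProb <= 1)
  structure(list(keepProb = keepProb, spuriousProb = spuriousProb),
            class = "RaterModel")
}

#' Generate a phantom tractogram with a known true bundle
#'
#' Core streamlines run bottom-to-top through the grid along a common
#' curving centerline, each offset by a random radial displacement that
#' widens towards the top (a fan) plus small per-point jitter, so their
#' density support is one spatially coherent tube. Distractors are straight
#' or mildly curved polylines placed away from, or crossing, the tube.
#' Everything is deterministic given the seed.
#'
#' @param nCore,nDistractor streamline counts.
#' @param grid a [ReferenceGrid-class]; at least 20 voxels per axis.
#' @param seed integer seed.
#' @return A list with `tractogram` (core streamlines first, then
#'   distractors), and `truth`: a list with `core` and `distractors`
#'   ([Selection-class] objects partitioning all indices) and the generation
#'   parameters.
#' @examples
#' ph <- makePhantom(50, 20, seed = 1)
#' selectionSize(ph$truth$core)  # 50
#' @export
makePhantom <- function(nCore = 200L, nDistractor = 100L,
                        grid = ReferenceGrid(c(32L, 32L, 32L)), seed = 1L) {
  stopifnot(nCore >= 0L, nDistractor >= 0L)
  if (any(grid@shape < 20L))
    stop("phantom grid must be at least 20 voxels per axis")
  shape <- grid@shape
  # work in voxel coordinates, convert to world at the end
  zLo <- 3; zHi <- shape[3] - 4
  nPts <- 25L
  zs <- seq(zLo, zHi, length.out = nPts)
  tt <- (zs - zLo) / (zHi - zLo)
  cx <- shape[1] / 2 + 2.5 * sin(pi * tt)    # gentle C-curve in x
  cy <- shape[2] / 2 + 1.5 * (tt - 0.5)      # slight drift in y

  streamlines <- withSeed(seed, {
    core <- lapply(seq_len(nCore), function(i) {
      ang <- runif(1, 0, 2 * pi)
      rad <- abs(rnorm(1, 0, 1.0))
      rad <- min(rad, 2.5)
      spread <- 0.6 + 1.0 * tt               # fan: wider at the top
      vox <- cbind(cx + cos(ang) * rad * spread + rnorm(nPts, 0, 0.25),
                   cy + sin(ang) * rad * spread + rnorm(nPts, 0, 0.25),
                   zs)
      applyAffine(grid@affine, vox)
    })
    distract <- lapply(seq_len(nDistractor), function(i) {
      # random chord through the grid, kept clear of boundaries
      p0 <- runif(3, 3, shape - 4)
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      len <- runif(1, 8, min(shape) - 8)
      s <- seq(0, len, length.out = 15L)
      vox <- cbind(p0[1] + dir[1] * s, p0[2] + dir[2] * s, p0[3] + dir[3] * s)
      vox <- pmin(pmax(vox, 1), matrix(shape - 2, 15L, 3L, byrow = TRUE))
      vox <- vox + cbind(rnorm(15L, 0, 0.2), rnorm(15L, 0, 0.2),
                         rnorm(15L, 0, 0.2))
      applyAffine(grid@affine, vox)
    })
    c(core, distract)
  })
  id <- sprintf("phantom-seed%d", seed)
  tract <- Tractogram(streamlines, grid, id = id)
  truth <- list(
    core = Selection(seq_len(nCore) - 1L, tract),
    distractors = Selection(nCore + seq_len(nDistractor) - 1L, tract),
    params = list(nCore = nCore, nDistractor = nDistractor, seed = seed))
  list(tractogram = tract, truth = truth)
}

#' Simulate one rater's segmentation of the phantom bundle
#'
#' Independent per-streamline decisions: each core streamline is included
#' with probability `model$keepProb`, each distractor with
#' `model$spuriousProb`.
#'
#' @param truth the `truth` element of [makePhantom()]'s result.
#' @param model a [raterModel()].
#' @param seed integer seed.
#' @return A [Selection-class] on the phantom tractogram.
#' @export
simulateRater <- function(truth, model, seed = 1L) {
  stopifnot(inherits(model, "RaterModel"))
  core <- selectionIndices(truth$core)
  dis <- selectionIndices(truth$distractors)
  picked <- withSeed(seed, {
    c(core[runif(length(core)) < model$keepProb],
      dis[runif(length(dis)) < model$spuriousProb])
  })
  Selection(picked, parentId(truth$core))
}

#' Simulate a full blinded triplication study
#'
#' Generates `nSubjects` phantoms, triplicates each (original / X-flip /
#' integer-voxel translation) under anonymized names, and has every
#' simulated rater segment all anonymized datasets with fresh seeds — each
#' replicate of a subject gets an independent Bernoulli draw, which is what
#' makes intra-rater agreement imperfect. Raters work in the variant's own
#' coordinate space; the Bernoulli decisions are index-based, so the
#' returned bundle is the variant-space geometry of the drawn indices.
#'
#' @param nSubjects number of phantom subjects.
#' @param nExperts,nNonexperts rater counts per group.
#' @param expertModel,nonexpertModel [raterModel()] objects.
#' @param nCore,nDistractor phantom composition per subject.
#' @param grid [ReferenceGrid-class] shared by all subjects.
#' @param translation integer(3) voxel shift for translated variants.
#' @param seed master seed; everything downstream is derived from it.
#' @return A list with `parents` (named list of phantom tractograms by
#'   subject), `truths`, `manifest` (combined `StudyManifest`), `raters`
#'   (data frame of rater id and group), and `bundles`: per rater, a named
#'   list of variant-space bundle [Tractogram-class]s keyed by anonymized
#'   dataset name — exactly what [deanonymize()] consumes.
#' @export
simulateStudy <- function(nSubjects = 5L, nExperts = 3L, nNonexperts = 3L,
                          expertModel = raterModel(0.9, 0.01),
                          nonexpertModel = raterModel(0.9, 0.10),
                          nCore = 200L, nDistractor = 100L,
                          grid = ReferenceGrid(c(32L, 32L, 32L)),
                          translation = c(2L, 3L, 1L), seed = 42L) {
  stopifnot(nSubjects >= 1L, nExperts + nNonexperts >= 2L)
  seeds <- childSeeds(seed, 2L * nSubjects + 1L)
  phantoms <- lapply(seq_len(nSubjects), function(i)
    makePhantom(nCore, nDistractor, grid, seed = seeds[i]))
  names(phantoms) <- vapply(phantoms, function(p) tractId(p$tractogram),
                            character(1))
  trips <- lapply(seq_len(nSubjects), function(i)
    makeTriplicates(phantoms[[i]]$tractogram, translation = translation,
                    seed = seeds[nSubjects + i]))
  manifest <- combineManifests(lapply(trips, `[[`, "manifest"))

  raters <- data.frame(
    rater = c(sprintf("expert%02d", seq_len(nExperts)),
              sprintf("nonexpert%02d", seq_len(nNonexperts))),
    group = rep(c("expert", "nonexpert"), c(nExperts, nNonexperts)),
    stringsAsFactors = FALSE)
  raterSeeds <- childSeeds(seeds[2L * nSubjects + 1L], nrow(raters))

  bundles <- list()
  for (r in seq_len(nrow(raters))) {
    model <- if (raters$group[r] == "expert") expertModel else nonexpertModel
    taskSeeds <- childSeeds(raterSeeds[r], nrow(manifest))
    perTask <- list()
    for (k in seq_len(nrow(manifest))) {
      name <- manifest$anonymized_name[k]
      subject <- manifest$subject[k]
      sel <- simulateRater(phantoms[[subject]]$truth, model,
                           seed = taskSeeds[k])
      variant <- trips[[match(subject, names(phantoms))]]$datasets[[name]]
      perTask[[name]] <- Tractogram(
        streamlines(variant, selectionIndices(sel) + 1L),
        grid, id = paste0(name, "-", raters$rater[r]))
    }
    bundles[[raters$rater[r]]] <- perTask
  }
  list(parents = lapply(phantoms, `[[`, "tractogram"),
       truths = lapply(phantoms, `[[`, "truth"),
       manifest = manifest,
       raters = raters,
       bundles = bundles,
       models = list(expert = expertModel, nonexpert = nonexpertModel),
       seed = seed)
}

#' Run the full scoring pipeline on a simulated study
#'
#' De-randomizes every rater's bundles, fuses triplicates, builds the
#' per-subject expert average segmentation, and assembles the intra-, inter-
#' and gold-standard score tables plus their median/IQR group summary.
#'
#' @param study result of [simulateStudy()].
#' @param measures pairwise measures to score.
#' @param minVote vote threshold for the average segmentation (count or
#'   ratio; default a strict majority of the expert group).
#' @param mode,fusion as in [interRaterScores()].
#' @param alpha significance threshold for group comparisons.
#' @return A list with `results` (list of `RaterResult`), `golds`, `scores`
#'   (one `ScoreTable`), and `summary` (from [studySummary()]).
#' @export
runStudy <- function(study, measures = c("dice_streamlines", "dice_voxels",
                                         "density_correlation"),
                     minVote = NULL, mode = "segments", fusion = "union",
                     alpha = 0.01) {
  parents <- study$parents
  results <- lapply(seq_len(nrow(study$raters)), function(r)
    deanonymize(study$bundles[[study$raters$rater[r]]], study$manifest,
                parents, rater = study$raters$rater[r],
                group = study$raters$group[r]))
  names(results) <- study$raters$rater

  experts <- results[study$raters$group == "expert"]
  if (is.null(minVote))
    minVote <- floor(length(experts) / 2) + 1L
  golds <- lapply(setNames(nm = names(parents)), function(subject) {
    fusedSel <- lapply(experts, fuseTriplicates, subject = subject,
                       method = fusion)
    buildGoldStandard(unname(fusedSel), parents[[subject]], minVote,
                      mode = mode)
  })

  intra <- do.call(rbind, lapply(results, intraRaterScores,
                                 parents = parents, measures = measures,
                                 mode = mode))
  inter <- interRaterScores(results, parents, measures = measures,
                            mode = mode, fusion = fusion)
  gold <- goldScores(results, golds, parents, measures = measures,
                     mode = mode, fusion = fusion)
  scores <- rbind(intra, inter, gold)
  rownames(scores) <- NULL
  class(scores) <- c("ScoreTable", "data.frame")
  list(results = results, golds = golds, scores = scores,
       summary = studySummary(scores, alpha = alpha))
}
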