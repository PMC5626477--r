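# Fisher z cap for |r| -> 1 (e.g. a voxel correlated with itself inside
# the seed mask); such voxels are flagged and excluded from inference.
Z_CAP_R <- 0.999999

# Correlation of every row of X (voxels x time) with the series s.
# Rows with zero variance yield NA.
rowCorsWith <- function(X, s) {
  Xc <- X - rowMeans(X)
  sc <- s - mean(s)
  denom <- sqrt(rowSums(Xc^2)) * sqrt(sum(sc^2))
  r <- as.numeric(Xc %*% sc) / denom
  r[denom == 0] <- NA_real_
  r
}

# Per-run (differential) seed-correlation map on the Fisher-z scale.
runSeedMap <- function(run, seedMask, referenceMask = NULL) {
  X <- run@data
  s <- colMeans(X[as.vector(seedMask), , drop = FALSE])
  r <- rowCorsWith(X, s)
  z <- fisherZ(pmin(pmax(r, -Z_CAP_R), Z_CAP_R))
  if (!is.null(referenceMask)) {
    sref <- colMeans(X[as.vector(referenceMask), , drop = FALSE])
    rref <- rowCorsWith(X, sref)
    z <- z - fisherZ(pmin(pmax(rref, -Z_CAP_R), Z_CAP_R))
  }
  z
}

#' Per-subject seed-correlation change map
#'
#' For one subject, computes for every run of each day the per-voxel
#' Fisher-z correlation with the mean seed-ROI series (optionally the
#' differential correlation: z(corr with seed) minus z(corr with
#' reference)), averages the maps over runs within each day, and returns
#' the day-B-minus-day-A difference as a 3-D array. Correlations of
#' magnitude 1 (e.g. voxels inside the seed) are capped at
#' `atanh(0.999999)`; voxels inside the seed/reference masks are flagged
#' via the `flaggedMask` attribute and should be excluded from peak
#' reporting. Constant voxel series give `NA` with a count in the
#' `nUndefined` attribute.
#'
#' @param runsDayA,runsDayB lists of [VoxelRun-class] objects for the two
#'   contrasted days (e.g. the four feedback runs of day1 and day4).
#' @param seedMask logical 3-D seed mask.
#' @param referenceMask optional logical 3-D reference mask for the
#'   differential map; `NULL` for a plain seed map.
#' @return 3-D numeric array (day B mean map minus day A mean map) with
#'   attributes `flaggedMask` and `nUndefined`.
#' @export
seedChangeMap <- function(runsDayA, runsDayB, seedMask, referenceMask = NULL) {
  stopifnot(length(runsDayA) >= 1L, length(runsDayB) >= 1L)
  shape <- runsDayA[[1]]@gridShape
  dayMean <- function(runs) {
    maps <- vapply(runs, runSeedMap, numeric(prod(shape)),
                   seedMask = seedMask, referenceMask = referenceMask)
    rowMeans(maps)
  }
  change <- dayMean(runsDayB) - dayMean(runsDayA)
  out <- array(change, dim = shape)
  flagged <- seedMask
  if (!is.null(referenceMask)) flagged <- flagged | referenceMask
  attr(out, "flaggedMask") <- flagged
  attr(out, "nUndefined") <- sum(is.na(change))
  out
}

#' Stream per-subject voxel change maps for a synthetic cohort
#'
#' Convenience driver that, for each subject, generates the voxel runs of
#' the two contrasted days, computes the subject's (differential)
#' seed-correlation change map, and discards the runs — keeping memory
#' bounded to one subject's runs at a time.
#'
#' @param spec a [VoxelGridSpec-class].
#' @param cohort a [CohortSpec-class].
#' @param seedRoi,referenceRoi ROI names (`"target1"`, `"target2"`,
#'   `"control"`); `referenceRoi = NULL` for a plain seed map.
#' @param dayA,dayB contrasted days.
#' @param runTypes run types entering the maps (default feedback runs).
#' @return list of per-subject change arrays (see [seedChangeMap()]),
#'   with attribute `masks`.
#' @export
subjectChangeMaps <- function(spec, cohort, seedRoi = "target1",
                              referenceRoi = "control",
                              dayA = "day1", dayB = "day4",
                              runTypes = "feedback") {
  masks <- roiMasks(spec)
  seedMask <- masks[[seedRoi]]
  refMask <- if (is.null(referenceRoi)) NULL else masks[[referenceRoi]]
  subjects <- sprintf("sub%02d", seq_len(cohort@nSubjects))
  maps <- lapply(subjects, function(subj) {
    runsA <- generateVoxelCohort(spec, cohort, days = dayA,
                                 runTypes = runTypes, subjects = subj)
    runsB <- generateVoxelCohort(spec, cohort, days = dayB,
                                 runTypes = runTypes, subjects = subj)
    seedChangeMap(runsA, runsB, seedMask, refMask)
  })
  names(maps) <- subjects
  attr(maps, "masks") <- masks
  maps
}

# Stack per-subject change arrays into a subjects x voxels matrix.
stackChangeMaps <- function(changeMaps) {
  shape <- dim(changeMaps[[1]])
  X <- t(vapply(changeMaps, as.numeric, numeric(prod(shape))))
  list(X = X, shape = shape)
}

#' Across-subject t-test map
#'
#' One-sample t-test of the per-subject change maps against zero at every
#' voxel, identifying voxels with a consistent change across subjects.
#' Voxels undefined (`NA`) in any subject are excluded and counted.
#'
#' @param changeMaps list of per-subject 3-D change arrays (all the same
#'   shape), e.g. from [subjectChangeMaps()]; at least 3 subjects.
#' @return a list: `t` and `p` (3-D arrays; two-tailed p), `nSubjects`,
#'   `df`, `nExcluded`.
#' @export
groupTtestMap <- function(changeMaps) {
  n <- length(changeMaps)
  if (n < 3L) stop("need at least 3 subjects")
  st <- stackChangeMaps(changeMaps)
  X <- st$X
  ok <- colSums(is.na(X)) == 0L
  m <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  t <- m / (sdv / sqrt(n))
  degenerate <- which(ok & sdv == 0)
  t[degenerate] <- ifelse(m[degenerate] == 0, 0, sign(m[degenerate]) * Inf)
  t[!ok] <- NA
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  list(t = array(t, st$shape), p = array(p, st$shape),
       nSubjects = n, df = n - 1, nExcluded = sum(!ok))
}

#' Multi-threshold cluster-size permutation correction
#'
#' Familywise-error control for the group change map, following the
#' day-label permutation scheme: because the per-subject statistic is a
#' paired day difference, exchanging a subject's day labels is exactly a
#' sign flip of that subject's change map. For each permutation the group
#' t map is recomputed under random per-subject sign flips; at each
#' voxelwise p threshold the size of the largest suprathreshold
#' 6-connected cluster is recorded, giving a null distribution of
#' maximum cluster sizes per threshold. Observed clusters at least as
#' large as the threshold's minimum significant size survive, and the
#' union mask collects voxels surviving at any threshold.
#'
#' By default (`jointCalibration = TRUE`) the per-threshold minimum
#' sizes are calibrated jointly on the permutation null: the
#' per-threshold level is tightened until the probability that *any*
#' threshold yields a surviving null cluster is at most `alpha`, so the
#' union mask itself controls the familywise error (a max-statistic
#' correction across the threshold family). With
#' `jointCalibration = FALSE` each threshold is controlled marginally at
#' `alpha` (one more than the `1 - alpha` quantile of its own
#' max-cluster null) and the union error rate can exceed `alpha`.
#'
#' Sign flips leave each voxel's sum of squares unchanged, so permuted t
#' statistics are computed from the flipped means alone (exact, not an
#' approximation).
#'
#' @param changeMaps list of per-subject 3-D change arrays (>= 5
#'   subjects). Voxels `NA` in any subject are excluded from inference.
#' @param thresholds voxelwise two-tailed p thresholds (default the
#'   study's 0.05, 0.01, 0.005, 0.001, 0.0005).
#' @param nPermutations number of sign-flip permutations (default 5000;
#'   at least 100).
#' @param seed RNG seed.
#' @param alpha cluster-level familywise error target.
#' @param jointCalibration calibrate the threshold family jointly so the
#'   union mask controls the familywise error at `alpha` (default);
#'   otherwise control each threshold marginally.
#' @return a [ClusterCorrectionResult-class].
#' @export
clusterPermutationCorrect <- function(changeMaps,
                                      thresholds = c(0.05, 0.01, 0.005,
                                                     0.001, 0.0005),
                                      nPermutations = 5000L, seed = 1L,
                                      alpha = 0.05, jointCalibration = TRUE) {
  nPermutations <- as.integer(nPermutations)
  if (nPermutations < 100L) stop("nPermutations must be at least 100")
  if (length(thresholds) == 0L) stop("thresholds must be nonempty")
  n <- length(changeMaps)
  if (n < 5L) stop("need at least 5 subjects")
  st <- stackChangeMaps(changeMaps)
  X <- st$X
  shape <- st$shape
  dims <- as.integer(shape)
  ok <- colSums(is.na(X)) == 0L
  X[, !ok] <- 0
  df <- n - 1
  tCrit <- stats::qt(1 - thresholds / 2, df = df)
  SS <- colSums(X^2)
  tFromMeans <- function(m) {
    varv <- (SS - n * m^2) / df
    t <- m / sqrt(varv / n)
    t[varv <= 0] <- 0
    t[!ok] <- 0
    t
  }
  obsT <- tFromMeans(colMeans(X))
  nThr <- length(thresholds)
  nullMax <- matrix(0L, nPermutations, nThr)
  withSeed(seed, {
    block <- 200L
    done <- 0L
    while (done < nPermutations) {
      b <- min(block, nPermutations - done)
      S <- matrix(sample(c(-1, 1), b * n, replace = TRUE), b, n)
      M <- (S %*% X) / n
      for (i in seq_len(b)) {
        tp <- abs(tFromMeans(M[i, ]))
        for (j in seq_len(nThr)) {
          nullMax[done + i, j] <-
            .maxClusterSize6(tp > tCrit[j], dims)
        }
      }
      done <- done + b
    }
  })
  minSizeAt <- function(level) {
    vapply(seq_len(nThr), function(j)
      as.integer(stats::quantile(nullMax[, j], 1 - level, type = 1)) + 1L,
      integer(1))
  }
  if (jointCalibration && nThr > 1L) {
    # tighten the shared per-threshold level until the permutation
    # probability of any null cluster surviving anywhere is <= alpha
    levels <- sort(unique(c(alpha, alpha / 2^(seq_len(12)))), decreasing = TRUE)
    minSizes <- minSizeAt(alpha)
    for (lv in levels) {
      cand <- minSizeAt(lv)
      jointRate <- mean(apply(
        nullMax >= matrix(cand, nPermutations, nThr, byrow = TRUE), 1, any))
      minSizes <- cand
      if (jointRate <= alpha) break
    }
  } else {
    minSizes <- minSizeAt(alpha)
  }
  survivorMasks <- vector("list", nThr)
  names(survivorMasks) <- as.character(thresholds)
  tab <- data.frame(threshold = thresholds, tCrit = tCrit,
                    minClusterSize = NA_integer_,
                    maxObservedCluster = NA_integer_,
                    nSurvivingVoxels = NA_integer_)
  absT <- abs(obsT)
  for (j in seq_len(nThr)) {
    minSize <- minSizes[j]
    mask <- array(absT > tCrit[j], dim = shape)
    labels <- .labelClusters6(mask, dims)
    sizes <- tabulate(labels[labels > 0])
    keep <- which(sizes >= minSize)
    surv <- array(labels %in% keep & labels > 0, dim = shape)
    survivorMasks[[j]] <- surv
    tab$minClusterSize[j] <- minSize
    tab$maxObservedCluster[j] <- if (length(sizes)) max(sizes) else 0L
    tab$nSurvivingVoxels[j] <- sum(surv)
  }
  union <- Reduce(`|`, survivorMasks)
  new("ClusterCorrectionResult", table = tab, unionMask = union,
      survivorMasks = survivorMasks, nullMaxSizes = nullMax,
      nPermutations = nPermutations, alpha = alpha, connectivity = "6",
      seed = as.integer(seed))
}

#' Surviving clusters and their peaks
#'
#' Tabulates the 6-connected clusters of a survivor mask, reporting each
#' cluster's size and peak voxel (largest |t|). Peak search never returns
#' a voxel inside `excludeMask` (the seed/reference ROIs, whose values
#' are self-correlations by construction); clusters with no eligible
#' voxel report an `NA` peak.
#'
#' @param tMap 3-D t-statistic array.
#' @param mask logical 3-D array of surviving voxels (e.g.
#'   `unionMask(result)`).
#' @param excludeMask optional logical 3-D array of voxels ineligible as
#'   peaks.
#' @return data.frame: `cluster`, `size`, `peakI`, `peakJ`, `peakK`,
#'   `peakT`, ordered by decreasing size.
#' @export
clusterPeaks <- function(tMap, mask, excludeMask = NULL) {
  dims <- as.integer(dim(mask))
  labels <- .labelClusters6(mask, dims)
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (length(ids) == 0L)
    return(data.frame(cluster = integer(), size = integer(),
                      peakI = integer(), peakJ = integer(),
                      peakK = integer(), peakT = numeric()))
  rows <- lapply(ids, function(id) {
    vox <- which(labels == id)
    eligible <- vox
    if (!is.null(excludeMask)) eligible <- vox[!as.vector(excludeMask)[vox]]
    if (length(eligible) == 0L) {
      return(data.frame(cluster = id, size = length(vox), peakI = NA_integer_,
                        peakJ = NA_integer_, peakK = NA_integer_,
                        peakT = NA_real_))
    }
    peak <- eligible[which.max(abs(as.vector(tMap)[eligible]))]
    co <- arrayInd(peak, dims)
    data.frame(cluster = id, size = length(vox), peakI = co[1], peakJ = co[2],
               peakK = co[3], peakT = as.vector(tMap)[peak])
  })
  out <- do.call(rbind, rows)
  out[order(-out$size), , drop = FALSE]
}
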