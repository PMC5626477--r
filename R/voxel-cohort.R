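#' Talairach coordinates of the trained ROIs
#'
#' The three 4-mm-sphere training ROIs of the study this package
#' simulates: target1 in left superior temporal sulcus, target2 in left
#' somatosensory cortex, control in right inferior parietal lobule.
#' These span more than 100 mm in x, so they only fit grids at least
#' about 110 mm across (e.g. `gridShape = c(48, 48, 48)` at 3.2 mm voxels
#' with the centered affine); the default 24^3 demonstration grid uses
#' synthetic in-grid centers instead.
#'
#' @return a 3x3 matrix of mm coordinates (rows target1, target2, control).
#' @examples
#' talairachCenters()
#' @export
talairachCenters <- function() {
  m <- rbind(target1 = c(-49, -29, 0),
             target2 = c(-54, 14, 39),
             control = c(49, -50, 42))
  colnames(m) <- c("x", "y", "z")
  m
}

# mm coordinates of every voxel centre under the centered affine.
voxelCoordinates <- function(gridShape, voxelSizeMm) {
  g <- as.integer(gridShape)
  idx <- as.matrix(expand.grid(i = seq_len(g[1]), j = seq_len(g[2]),
                               k = seq_len(g[3])))
  sweep(idx, 2, (g + 1) / 2) * voxelSizeMm
}

# Voxel-centre mm coordinate of a fractional grid position.
gridToMm <- function(index, gridShape, voxelSizeMm) {
  (index - (as.integer(gridShape) + 1) / 2) * voxelSizeMm
}

#' Spherical ROI mask on a voxel grid
#'
#' Returns the logical 3-D mask of voxels whose centre lies within
#' `radiusMm` of `centerMm` (centered affine: the grid centre is the mm
#' origin). Fails if the sphere does not fit inside the grid, reporting
#' the minimum grid shape required.
#'
#' @param gridShape integer length-3 grid dimensions.
#' @param voxelSizeMm isotropic voxel size (mm).
#' @param centerMm length-3 mm coordinates of the sphere centre.
#' @param radiusMm sphere radius (mm).
#' @return logical array of dimension `gridShape`.
#' @examples
#' sum(sphereMask(c(24, 24, 24), 3.2, c(0, 0, 0), 4))
#' @export
sphereMask <- function(gridShape, voxelSizeMm, centerMm, radiusMm = 4) {
  g <- as.integer(gridShape)
  halfExtent <- g * voxelSizeMm / 2
  if (any(abs(centerMm) + radiusMm > halfExtent)) {
    needed <- ceiling(2 * (abs(centerMm) + radiusMm) / voxelSizeMm)
    stop("sphere at (", paste(centerMm, collapse = ", "),
         ") mm with radius ", radiusMm,
         " mm does not fit in the grid; minimum gridShape: c(",
         paste(pmax(needed, g), collapse = ", "), ")")
  }
  co <- voxelCoordinates(g, voxelSizeMm)
  d2 <- (co[, 1] - centerMm[1])^2 + (co[, 2] - centerMm[2])^2 +
        (co[, 3] - centerMm[3])^2
  array(d2 <= radiusMm^2, dim = g)
}

# Default synthetic in-grid ROI centres: voxel-centre positions at about
# 1/4, 3/4 and centre of the grid, mutually distant.
defaultRoiCenters <- function(gridShape, voxelSizeMm) {
  g <- as.integer(gridShape)
  at <- function(i, j, k) gridToMm(c(i, j, k), g, voxelSizeMm)
  m <- rbind(target1 = at(round(g[1] / 4), round(g[2] / 2), round(g[3] / 2)),
             target2 = at(round(3 * g[1] / 4), round(g[2] / 2), round(g[3] / 2)),
             control = at(round(g[1] / 2), round(g[2] / 2), round(3 * g[3] / 4)))
  colnames(m) <- c("x", "y", "z")
  m
}

# Default network coupling trajectory: reuse the ROI-level day matrices.
defaultCouplingTrajectory <- function(days = c("day1", "day2", "day3", "day4", "followup"),
                                      groupLabel = "ASD-like") {
  spec <- CohortSpec(nSubjects = 1L, groupLabel = groupLabel, days = days)
  out <- lapply(days, function(d) {
    m <- dayCorrMatrix(spec, d)
    dimnames(m) <- list(NETWORK_NAMES, NETWORK_NAMES)
    m
  })
  stats::setNames(out, days)
}

#' Construct a VoxelGridSpec
#'
#' Validates geometry on construction: every spherical mask must be
#' non-empty, the masks mutually disjoint, and each ROI-centre voxel a
#' member of its own mask.
#'
#' @param gridShape integer length-3 grid dimensions (default 24^3).
#' @param voxelSizeMm isotropic voxel size, default 3.2 mm.
#' @param roiCenters 3x3 mm-coordinate matrix (rows target1, target2,
#'   control); defaults to synthetic, mutually distant in-grid positions.
#'   Use [talairachCenters()] with a large enough grid for the study's
#'   printed coordinates.
#' @param roiRadiusMm ROI sphere radius (seed extraction, peak
#'   exclusion), default 4 mm.
#' @param networkRadiusMm radius of the coherent latent network around
#'   each centre, default 6 mm (networks extend beyond the feedback ROI).
#' @param couplingTrajectory named list of per-day 3x3 network correlation
#'   matrices (networks network1, network2, control_network).
#' @param voxelLoading correlation of a network voxel with its latent
#'   network signal, default 0.9.
#' @return a [VoxelGridSpec-class] object.
#' @examples
#' vs <- VoxelGridSpec()
#' vapply(roiMasks(vs), sum, 1)
#' @export
VoxelGridSpec <- function(gridShape = c(24L, 24L, 24L),
                          voxelSizeMm = 3.2,
                          roiCenters = defaultRoiCenters(gridShape, voxelSizeMm),
                          roiRadiusMm = 4,
                          networkRadiusMm = 6,
                          couplingTrajectory = defaultCouplingTrajectory(),
                          voxelLoading = 0.9) {
  spec <- new("VoxelGridSpec",
              gridShape = as.integer(gridShape),
              voxelSizeMm = as.numeric(voxelSizeMm),
              roiCenters = roiCenters, roiRadiusMm = as.numeric(roiRadiusMm),
              networkRadiusMm = as.numeric(networkRadiusMm),
              couplingTrajectory = couplingTrajectory,
              voxelLoading = as.numeric(voxelLoading))
  for (masks in list(roiMasks(spec), networkMasks(spec))) {
    counts <- vapply(masks, sum, numeric(1))
    if (any(counts == 0))
      stop("empty mask(s): ", paste(names(counts)[counts == 0], collapse = ", "))
    overlap <- Reduce(`+`, masks)
    if (any(overlap > 1)) stop("sphere masks overlap; move the centres apart")
  }
  masks <- roiMasks(spec)
  for (r in seq_len(3)) {
    ci <- round(spec@roiCenters[r, ] / voxelSizeMm + (spec@gridShape + 1) / 2)
    if (!masks[[r]][ci[1], ci[2], ci[3]])
      stop("centre voxel of ", ROI_NAMES[r], " is not inside its own mask")
  }
  spec
}

#' Spherical ROI masks of a VoxelGridSpec
#'
#' @param spec a [VoxelGridSpec-class].
#' @return named list (`target1`, `target2`, `control`) of logical arrays.
#' @export
roiMasks <- function(spec) {
  stopifnot(is(spec, "VoxelGridSpec"))
  out <- lapply(seq_len(3), function(r)
    sphereMask(spec@gridShape, spec@voxelSizeMm, spec@roiCenters[r, ],
               spec@roiRadiusMm))
  stats::setNames(out, ROI_NAMES)
}

#' Latent-network masks of a VoxelGridSpec
#'
#' Spheres of `networkRadiusMm` around the ROI centres: the voxels that
#' load on each latent network signal.
#'
#' @param spec a [VoxelGridSpec-class].
#' @return named list (`target1`, `target2`, `control`) of logical arrays.
#' @export
networkMasks <- function(spec) {
  stopifnot(is(spec, "VoxelGridSpec"))
  out <- lapply(seq_len(3), function(r)
    sphereMask(spec@gridShape, spec@voxelSizeMm, spec@roiCenters[r, ],
               spec@networkRadiusMm))
  stats::setNames(out, ROI_NAMES)
}

#' Voxel-to-network assignment of a VoxelGridSpec
#'
#' @param spec a [VoxelGridSpec-class].
#' @return character array of dimension `gridShape` with values
#'   `network1`, `network2`, `control_network`, `background`.
#' @export
networkAssignment <- function(spec) {
  masks <- networkMasks(spec)
  a <- array("background", dim = spec@gridShape)
  a[masks$target1] <- "network1"
  a[masks$target2] <- "network2"
  a[masks$control] <- "control_network"
  a
}

#' Generate synthetic voxel-grid runs
#'
#' For each requested subject/day/run, simulates three latent network
#' signals whose correlations follow that day's coupling matrix, assigns
#' each network sphere's voxels (radius `networkRadiusMm`) a noisy copy
#' of their latent (`voxelLoading` sets the voxel-latent correlation)
#' and fills all remaining voxels with independent unit-variance noise.
#' AR(1) temporal structure follows the cohort spec's `arCoeff`; drift
#' is omitted.
#'
#' Voxel runs are large; restrict `days`, `runTypes` or `subjects` to
#' keep memory bounded, or use [subjectChangeMaps()] which streams runs
#' one subject at a time.
#'
#' @param spec a [VoxelGridSpec-class].
#' @param cohort a [CohortSpec-class] providing subjects, days, run
#'   structure, nTR, AR coefficient and base seed. Days must be present
#'   in `spec@couplingTrajectory`.
#' @param days,runTypes,subjects optional subsets.
#' @return named list of [VoxelRun-class] objects with attribute `masks`
#'   (from [roiMasks()]).
#' @export
generateVoxelCohort <- function(spec, cohort, days = NULL, runTypes = NULL,
                                subjects = NULL) {
  stopifnot(is(spec, "VoxelGridSpec"), is(cohort, "CohortSpec"))
  if (is.null(days)) days <- cohort@days
  missingDays <- setdiff(days, names(spec@couplingTrajectory))
  if (length(missingDays))
    stop("couplingTrajectory has no entry for: ", paste(missingDays, collapse = ", "))
  allSubjects <- sprintf("sub%02d", seq_len(cohort@nSubjects))
  if (is.null(subjects)) subjects <- allSubjects
  rpd <- cohort@runsPerDay
  types <- c(rep("rest", rpd[["rest_pre"]]), rep("feedback", rpd[["feedback"]]),
             rep("rest", rpd[["rest_post"]]))
  nets <- networkMasks(spec)
  out <- list()
  for (subj in subjects) {
    for (day in days) {
      for (i in seq_along(types)) {
        if (!is.null(runTypes) && !types[i] %in% runTypes) next
        out[[paste(subj, day, sprintf("run%02d", i), sep = ".")]] <-
          generateVoxelRun(spec, cohort, subj, day, i, types[i], nets)
      }
    }
  }
  attr(out, "masks") <- roiMasks(spec)
  attr(out, "networkMasks") <- nets
  out
}

# One voxel run; seeded per (cohort seed, subject, day, run) so any subset
# of the cohort regenerates identically. Network voxels load on their
# latent via the networkMasks spheres.
generateVoxelRun <- function(spec, cohort, subject, day, runIdx, runType,
                             masks = networkMasks(spec)) {
  nTR <- cohort@nTR
  nVox <- prod(spec@gridShape)
  a <- spec@voxelLoading
  coupling <- spec@couplingTrajectory[[day]]
  if (!isPSD(coupling)) {
    if (!cohort@repairPsd)
      stop("coupling matrix for ", day, " is not positive semidefinite")
    coupling <- nearestPSD(coupling)
  }
  withSeed(childSeed(cohort@seed, subject, day, runIdx), {
    latents <- simulateCorrelatedSeries(nTR, coupling, cohort@arCoeff)
    data <- matrix(stats::rnorm(nVox * nTR), nVox, nTR)
    for (r in seq_len(3)) {
      v <- which(masks[[r]])
      data[v, ] <- a * matrix(latents[, r], length(v), nTR, byrow = TRUE) +
        sqrt(1 - a^2) * data[v, , drop = FALSE]
    }
    new("VoxelRun", subject = subject, day = day, runIndex = as.integer(runIdx),
        runType = runType, data = data, gridShape = spec@gridShape)
  })
}
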