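#' @import methods
NULL

ROI_NAMES <- c("target1", "target2", "control")
PAIR_NAMES <- c("t1t2", "t1c", "t2c")
NETWORK_NAMES <- c("network1", "network2", "control_network")

#' CohortSpec: design of a synthetic neurofeedback cohort
#'
#' Describes one arm of a simulated covert-neurofeedback study: how many
#' subjects, which training days, how many rest/feedback runs per day, the
#' sampling grid (number of TRs and TR duration), the day-1 inter-ROI
#' correlation structure and its programmed day-by-day trajectory, and the
#' temporal properties (AR(1) coefficient, slow drift, innovation scale) of
#' the generated BOLD-like signals.
#'
#' @slot nSubjects number of subjects in the arm.
#' @slot groupLabel `"ASD-like"` or `"TD-like"`.
#' @slot days ordered character vector of day labels.
#' @slot runsPerDay named integer vector with elements `rest_pre`,
#'   `feedback`, `rest_post`.
#' @slot nTR samples per run.
#' @slot trSeconds sampling interval in seconds.
#' @slot baselineCorr 3x3 day-1 inter-ROI correlation matrix
#'   (order target1, target2, control).
#' @slot dayDeltas numeric matrix, one row per day, columns `t1t2`, `t1c`,
#'   `t2c`: additive change of each pairwise correlation relative to
#'   baseline on that day.
#' @slot arCoeff AR(1) coefficient in [0, 1), shared across ROIs.
#' @slot driftAmplitude amplitude of the slow sinusoidal drift, in units of
#'   the (unit) stationary signal SD.
#' @slot noiseSd innovation standard deviation.
#' @slot seed integer RNG seed.
#' @slot repairPsd if `TRUE`, non-positive-semidefinite requested
#'   correlation matrices are repaired by eigenvalue clipping instead of
#'   rejected.
#' @seealso [CohortSpec()] for the user constructor.
#' @export
setClass("CohortSpec",
  representation(
    nSubjects = "integer",
    groupLabel = "character",
    days = "character",
    runsPerDay = "integer",
    nTR = "integer",
    trSeconds = "numeric",
    baselineCorr = "matrix",
    dayDeltas = "matrix",
    arCoeff = "numeric",
    driftAmplitude = "numeric",
    noiseSd = "numeric",
    seed = "integer",
    repairPsd = "logical"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (!object@groupLabel %in% c("ASD-like", "TD-like"))
    msg <- c(msg, "groupLabel must be 'ASD-like' or 'TD-like'")
  if (length(object@days) < 1L || anyDuplicated(object@days))
    msg <- c(msg, "days must be a non-empty vector of unique labels")
  if (!all(c("rest_pre", "feedback", "rest_post") %in% names(object@runsPerDay)))
    msg <- c(msg, "runsPerDay needs elements rest_pre, feedback, rest_post")
  if (object@nTR < 2L) msg <- c(msg, "nTR must be >= 2")
  if (object@trSeconds <= 0) msg <- c(msg, "trSeconds must be positive")
  b <- object@baselineCorr
  if (!all(dim(b) == c(3L, 3L)) || max(abs(b - t(b))) > 1e-12 ||
      max(abs(diag(b) - 1)) > 1e-12)
    msg <- c(msg, "baselineCorr must be a symmetric 3x3 matrix with unit diagonal")
  if (any(abs(b) > 1 + 1e-12)) msg <- c(msg, "baselineCorr entries must lie in [-1, 1]")
  d <- object@dayDeltas
  if (nrow(d) != length(object@days) || !identical(colnames(d), PAIR_NAMES))
    msg <- c(msg, "dayDeltas must have one row per day and columns t1t2, t1c, t2c")
  if (object@arCoeff < 0 || object@arCoeff >= 1)
    msg <- c(msg, "arCoeff must lie in [0, 1)")
  if (object@driftAmplitude < 0) msg <- c(msg, "driftAmplitude must be >= 0")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
  if (length(msg)) msg else TRUE
})

#' RoiRun: one run's three-ROI time series
#'
#' Holds the mean-signal time series of the three trained regions of
#' interest (target1, target2, control) for a single rest or feedback run,
#' plus run identity metadata.
#'
#' @slot subject subject identifier.
#' @slot day day label.
#' @slot runIndex 1-based index of the run within its day.
#' @slot runType `"rest"` or `"feedback"`.
#' @slot series numeric matrix, `nTR` rows by 3 columns
#'   (target1, target2, control); no missing values.
#' @seealso [RoiRun()], [generateRoiCohort()]
#' @export
setClass("RoiRun",
  representation(
    subject = "character",
    day = "character",
    runIndex = "integer",
    runType = "character",
    series = "matrix"
  )
)

setValidity("RoiRun", function(object) {
  msg <- character()
  s <- object@series
  if (ncol(s) != 3L || !identical(colnames(s), ROI_NAMES))
    msg <- c(msg, "series must have 3 columns named target1, target2, control")
  if (nrow(s) < 2L) msg <- c(msg, "series must have at least 2 samples")
  if (anyNA(s)) msg <- c(msg, "series must not contain missing values")
  if (!object@runType %in% c("rest", "feedback"))
    msg <- c(msg, "runType must be 'rest' or 'feedback'")
  if (length(msg)) msg else TRUE
})

#' FeedbackLog: per-TR decision trace of a feedback run
#'
#' Records, for every TR after the first, the signal increments of the
#' three ROIs, whether the two-point feedback rule fired, and the
#' cumulative puzzle bookkeeping (pieces revealed, 25-piece boards
#' completed).
#'
#' @slot subject,day,runIndex run identity.
#' @slot decisions data.frame with columns `tr`, `dTarget1`, `dTarget2`,
#'   `dControl`, `fired` (one row per TR transition).
#' @slot piecesRevealed number of fired decisions.
#' @slot boardsCompleted `floor(piecesRevealed / boardSize)`.
#' @slot boardSize puzzle pieces per board (25).
#' @seealso [runFeedbackSession()]
#' @export
setClass("FeedbackLog",
  representation(
    subject = "character",
    day = "character",
    runIndex = "integer",
    decisions = "data.frame",
    piecesRevealed = "integer",
    boardsCompleted = "integer",
    boardSize = "integer"
  )
)

setValidity("FeedbackLog", function(object) {
  msg <- character()
  d <- object@decisions
  need <- c("tr", "dTarget1", "dTarget2", "dControl", "fired")
  if (!all(need %in% names(d)))
    msg <- c(msg, paste("decisions needs columns", paste(need, collapse = ", ")))
  else {
    if (object@piecesRevealed != sum(d$fired))
      msg <- c(msg, "piecesRevealed must equal the number of fired decisions")
    if (object@boardsCompleted != object@piecesRevealed %/% object@boardSize)
      msg <- c(msg, "boardsCompleted must equal floor(piecesRevealed / boardSize)")
  }
  if (length(msg)) msg else TRUE
})

#' VoxelGridSpec: geometry and coupling of a synthetic voxel grid
#'
#' Describes a small 3-D voxel grid carrying three spherical ROI masks and
#' three latent networks (network1 seeded at target1, network2 at target2,
#' a control network at the control ROI) whose inter-network coupling
#' follows a per-day trajectory. Voxels inside a sphere load on their
#' network's latent signal; all remaining voxels are independent
#' background noise.
#'
#' Physical coordinates use a centered affine: voxel index `(i, j, k)`
#' (1-based) maps to `(i - (shape+1)/2) * voxelSizeMm` mm, so the grid
#' centre is at the origin. A sphere mask is the set of voxels whose
#' centre lies within `roiRadiusMm` of the ROI centre.
#'
#' @slot gridShape integer length-3 grid dimensions.
#' @slot voxelSizeMm isotropic voxel size in mm.
#' @slot roiCenters 3x3 numeric matrix of mm coordinates, one row per ROI
#'   (target1, target2, control).
#' @slot roiRadiusMm radius (mm) of the ROI spheres used for seed
#'   extraction and peak exclusion.
#' @slot networkRadiusMm radius (mm) of the coherent network around each
#'   centre (the voxels loading on the latent signal); at least
#'   `roiRadiusMm`, reflecting that trained changes spread over networks
#'   larger than the feedback ROI itself.
#' @slot couplingTrajectory named list, one 3x3 network correlation matrix
#'   per day (order network1, network2, control_network).
#' @slot voxelLoading correlation of a network voxel with its latent
#'   signal, in (0, 1].
#' @seealso [VoxelGridSpec()], [generateVoxelCohort()], [sphereMask()]
#' @export
setClass("VoxelGridSpec",
  representation(
    gridShape = "integer",
    voxelSizeMm = "numeric",
    roiCenters = "matrix",
    roiRadiusMm = "numeric",
    networkRadiusMm = "numeric",
    couplingTrajectory = "list",
    voxelLoading = "numeric"
  )
)

setValidity("VoxelGridSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be three positive integers")
  if (object@voxelSizeMm <= 0) msg <- c(msg, "voxelSizeMm must be positive")
  if (!all(dim(object@roiCenters) == c(3L, 3L)))
    msg <- c(msg, "roiCenters must be a 3x3 matrix (ROI x coordinate)")
  if (object@roiRadiusMm <= 0) msg <- c(msg, "roiRadiusMm must be positive")
  if (object@networkRadiusMm < object@roiRadiusMm)
    msg <- c(msg, "networkRadiusMm must be at least roiRadiusMm")
  if (object@voxelLoading <= 0 || object@voxelLoading > 1)
    msg <- c(msg, "voxelLoading must lie in (0, 1]")
  for (m in object@couplingTrajectory) {
    if (!is.matrix(m) || !all(dim(m) == c(3L, 3L)) ||
        max(abs(m - t(m))) > 1e-12 || max(abs(diag(m) - 1)) > 1e-12) {
      msg <- c(msg, "couplingTrajectory entries must be symmetric 3x3 unit-diagonal matrices")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' VoxelRun: one run's voxel-grid time series
#'
#' Stores a flattened 4-D acquisition: a voxels-by-time matrix plus the
#' grid shape needed to restore the 3-D layout (column-major voxel order).
#'
#' @slot subject,day,runIndex,runType run identity.
#' @slot data numeric matrix, `prod(gridShape)` rows by `nTR` columns.
#' @slot gridShape integer length-3 grid dimensions.
#' @seealso [generateVoxelCohort()]
#' @export
setClass("VoxelRun",
  representation(
    subject = "character",
    day = "character",
    runIndex = "integer",
    runType = "character",
    data = "matrix",
    gridShape = "integer"
  )
)

setValidity("VoxelRun", function(object) {
  msg <- character()
  if (nrow(object@data) != prod(object@gridShape))
    msg <- c(msg, "data must have one row per voxel of gridShape")
  if (ncol(object@data) < 2L) msg <- c(msg, "data must have at least 2 time points")
  if (length(msg)) msg else TRUE
})

#' ClusterCorrectionResult: multi-threshold cluster-size correction
#'
#' Result of the cluster-size permutation correction of a group t map:
#' for each voxelwise p threshold, the permutation-derived minimum
#' significant cluster size and the mask of surviving voxels, plus the
#' union mask of voxels surviving at any threshold.
#'
#' @slot table data.frame with columns `threshold`, `tCrit`,
#'   `minClusterSize` (smallest surviving size), `maxObservedCluster`,
#'   `nSurvivingVoxels`.
#' @slot unionMask logical 3-D array: voxels surviving at >= 1 threshold.
#' @slot survivorMasks named list of per-threshold logical arrays.
#' @slot nullMaxSizes matrix of permutation max-cluster sizes
#'   (permutation x threshold).
#' @slot nPermutations,alpha,connectivity,seed correction parameters;
#'   connectivity is `"6"` (faces only).
#' @seealso [clusterPermutationCorrect()]
#' @export
setClass("ClusterCorrectionResult",
  representation(
    table = "data.frame",
    unionMask = "array",
    survivorMasks = "list",
    nullMaxSizes = "matrix",
    nPermutations = "integer",
    alpha = "numeric",
    connectivity = "character",
    seed = "integer"
  )
)
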