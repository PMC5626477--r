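#' Accessors for covertnf objects
#'
#' Small accessor generics for the S4 containers: `roiSeries()` returns the
#' nTR-by-3 signal matrix of a [RoiRun-class]; `subjectId()`, `dayLabel()`,
#' `runIndex()` and `runType()` return run identity fields; `decisions()`,
#' `piecesRevealed()` and `boardsCompleted()` expose a
#' [FeedbackLog-class]'s decision trace and puzzle bookkeeping;
#' `unionMask()` and `clusterTable()` expose a
#' [ClusterCorrectionResult-class]'s union survivor mask and per-threshold
#' summary table.
#'
#' @param x the object.
#' @return see the individual method descriptions above.
#' @name accessors
#' @aliases roiSeries subjectId dayLabel runIndex runType decisions
#'   piecesRevealed boardsCompleted unionMask clusterTable
NULL

#' @rdname accessors
#' @export
setGeneric("roiSeries", function(x) standardGeneric("roiSeries"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("dayLabel", function(x) standardGeneric("dayLabel"))
#' @rdname accessors
#' @export
setGeneric("runIndex", function(x) standardGeneric("runIndex"))
#' @rdname accessors
#' @export
setGeneric("runType", function(x) standardGeneric("runType"))
#' @rdname accessors
#' @export
setGeneric("decisions", function(x) standardGeneric("decisions"))
#' @rdname accessors
#' @export
setGeneric("piecesRevealed", function(x) standardGeneric("piecesRevealed"))
#' @rdname accessors
#' @export
setGeneric("boardsCompleted", function(x) standardGeneric("boardsCompleted"))
#' @rdname accessors
#' @export
setGeneric("unionMask", function(x) standardGeneric("unionMask"))
#' @rdname accessors
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' @rdname accessors
setMethod("roiSeries", "RoiRun", function(x) x@series)
#' @rdname accessors
setMethod("subjectId", "RoiRun", function(x) x@subject)
#' @rdname accessors
setMethod("dayLabel", "RoiRun", function(x) x@day)
#' @rdname accessors
setMethod("runIndex", "RoiRun", function(x) x@runIndex)
#' @rdname accessors
setMethod("runType", "RoiRun", function(x) x@runType)

#' @rdname accessors
setMethod("subjectId", "FeedbackLog", function(x) x@subject)
#' @rdname accessors
setMethod("dayLabel", "FeedbackLog", function(x) x@day)
#' @rdname accessors
setMethod("runIndex", "FeedbackLog", function(x) x@runIndex)
#' @rdname accessors
setMethod("decisions", "FeedbackLog", function(x) x@decisions)
#' @rdname accessors
setMethod("piecesRevealed", "FeedbackLog", function(x) x@piecesRevealed)
#' @rdname accessors
setMethod("boardsCompleted", "FeedbackLog", function(x) x@boardsCompleted)

#' @rdname accessors
setMethod("subjectId", "VoxelRun", function(x) x@subject)
#' @rdname accessors
setMethod("dayLabel", "VoxelRun", function(x) x@day)
#' @rdname accessors
setMethod("runIndex", "VoxelRun", function(x) x@runIndex)
#' @rdname accessors
setMethod("runType", "VoxelRun", function(x) x@runType)

#' @rdname accessors
setMethod("unionMask", "ClusterCorrectionResult", function(x) x@unionMask)
#' @rdname accessors
setMethod("clusterTable", "ClusterCorrectionResult", function(x) x@table)

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nSubjects, "subjects,", object@groupLabel, "\n")
  cat("  days:", paste(object@days, collapse = ", "), "\n")
  cat("  runs/day:", paste(names(object@runsPerDay), object@runsPerDay,
                           sep = "=", collapse = " "), "\n")
  cat("  nTR:", object@nTR, " TR:", object@trSeconds, "s",
      " AR(1):", object@arCoeff, " drift:", object@driftAmplitude, "\n")
  cat("  baseline r (t1t2, t1c, t2c):",
      paste(sprintf("%.3f", object@baselineCorr[upper.tri(object@baselineCorr)][c(1, 2, 3)]),
            collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "RoiRun", function(object) {
  cat(sprintf("RoiRun %s / %s / run %d (%s): %d TRs x 3 ROIs\n",
              object@subject, object@day, object@runIndex, object@runType,
              nrow(object@series)))
  invisible(NULL)
})

setMethod("show", "FeedbackLog", function(object) {
  cat(sprintf(
    "FeedbackLog %s / %s / run %d: %d decisions, %d pieces, %d boards\n",
    object@subject, object@day, object@runIndex, nrow(object@decisions),
    object@piecesRevealed, object@boardsCompleted))
  invisible(NULL)
})

setMethod("show", "VoxelGridSpec", function(object) {
  cat("VoxelGridSpec:", paste(object@gridShape, collapse = "x"),
      "grid,", object@voxelSizeMm, "mm voxels,",
      object@roiRadiusMm, "mm sphere ROIs\n")
  cat("  days:", paste(names(object@couplingTrajectory), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "VoxelRun", function(object) {
  cat(sprintf("VoxelRun %s / %s / run %d (%s): %s grid, %d TRs\n",
              object@subject, object@day, object@runIndex, object@runType,
              paste(object@gridShape, collapse = "x"), ncol(object@data)))
  invisible(NULL)
})

setMethod("show", "ClusterCorrectionResult", function(object) {
  cat("ClusterCorrectionResult:", object@nPermutations, "permutations,",
      object@connectivity, "-connectivity, alpha =", object@alpha, "\n", sep = "")
  print(object@table, row.names = FALSE)
  cat("union mask:", sum(object@unionMask), "voxels\n")
  invisible(NULL)
})
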