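#' Write / read a RoiRun as TSV with a JSON sidecar
#'
#' The TSV holds columns `tr_index`, `target1`, `target2`, `control`; run
#' metadata (subject, day, run index, run type) goes to a `.json` sidecar
#' next to the TSV. The round trip is lossless to full double precision.
#'
#' @param run a [RoiRun-class].
#' @param path TSV file path; the sidecar is `paste0(path, ".json")`.
#' @return `writeRoiRun()` returns `path` invisibly; `readRoiRun()`
#'   returns a [RoiRun-class].
#' @export
writeRoiRun <- function(run, path) {
  stopifnot(is(run, "RoiRun"))
  s <- run@series
  df <- data.frame(tr_index = seq_len(nrow(s)),
                   target1 = sprintf("%.17g", s[, 1]),
                   target2 = sprintf("%.17g", s[, 2]),
                   control = sprintf("%.17g", s[, 3]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(subject = run@subject, day = run@day,
               run_index = run@runIndex, run_type = run@runType,
               n_tr = nrow(s))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeRoiRun
#' @export
readRoiRun <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("ROI run TSV ", path, " has no data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  need <- c("tr_index", "target1", "target2", "control")
  if (!identical(header, need))
    stop("ROI run TSV ", path, ": line 1 must be the header ",
         paste(need, collapse = "\t"))
  bad <- which(lengths(fields) != 4L)
  if (length(bad))
    stop("ROI run TSV ", path, ": malformed line ", bad[1],
         " (expected 4 tab-separated fields, got ", lengths(fields)[bad[1]], ")")
  vals <- matrix(suppressWarnings(
    as.numeric(unlist(fields[-1]))), ncol = 4L, byrow = TRUE)
  if (anyNA(vals)) {
    badLine <- which(apply(is.na(vals), 1, any))[1] + 1L
    stop("ROI run TSV ", path, ": non-numeric value on line ", badLine)
  }
  metaPath <- paste0(path, ".json")
  meta <- if (file.exists(metaPath)) jsonlite::read_json(metaPath)
          else list(subject = "sub01", day = "day1", run_index = 1L,
                    run_type = "rest")
  RoiRun(vals[, 2:4], subject = meta$subject, day = meta$day,
         runIndex = as.integer(meta$run_index), runType = meta$run_type)
}

#' Write / read 3-D or 4-D grids as NIfTI
#'
#' Thin wrappers around RNifti for the package's voxel artifacts: 4-D
#' voxel runs, 3-D statistic maps, and integer-label ROI masks
#' (target1 = 1, target2 = 2, control = 3).
#'
#' @param x numeric/integer array (or, for `writeRoiMaskNifti()`, the
#'   named list of logical masks from [roiMasks()]).
#' @param path output `.nii`/`.nii.gz` path.
#' @param voxelSizeMm isotropic voxel size recorded in the header.
#' @return writers return `path` invisibly; readers return the array
#'   (`readRoiMaskNifti()` returns the named list of logical masks).
#' @export
writeNiftiGrid <- function(x, path, voxelSizeMm = 3.2) {
  img <- RNifti::asNifti(x, pixdim = rep(voxelSizeMm, length(dim(x))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeNiftiGrid
#' @export
readNiftiGrid <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}

#' @rdname writeNiftiGrid
#' @export
writeRoiMaskNifti <- function(x, path, voxelSizeMm = 3.2) {
  labels <- array(0L, dim = dim(x[[1]]))
  for (i in seq_along(x)) labels[x[[i]]] <- i
  writeNiftiGrid(labels, path, voxelSizeMm)
}

#' @rdname writeNiftiGrid
#' @export
readRoiMaskNifti <- function(path) {
  labels <- readNiftiGrid(path)
  out <- lapply(1:3, function(i) array(labels == i, dim = dim(labels)))
  stats::setNames(out, ROI_NAMES)
}

#' Write / read a FeedbackLog
#'
#' The decision trace goes to JSON lines (one decision per line); a
#' summary JSON (`paste0(path, ".summary.json")`) records the fired
#' count and board bookkeeping.
#'
#' @param log a [FeedbackLog-class].
#' @param path output `.jsonl` path.
#' @return `writeFeedbackLog()` returns `path` invisibly;
#'   `readFeedbackLog()` returns a [FeedbackLog-class].
#' @export
writeFeedbackLog <- function(log, path) {
  stopifnot(is(log, "FeedbackLog"))
  d <- log@decisions
  lines <- vapply(seq_len(nrow(d)), function(i)
    jsonlite::toJSON(as.list(d[i, ]), auto_unbox = TRUE, digits = NA),
    character(1))
  writeLines(lines, path)
  summary <- list(subject = log@subject, day = log@day,
                  run_index = log@runIndex,
                  pieces_revealed = log@piecesRevealed,
                  boards_completed = log@boardsCompleted,
                  board_size = log@boardSize)
  jsonlite::write_json(summary, paste0(path, ".summary.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeFeedbackLog
#' @export
readFeedbackLog <- function(path) {
  rows <- lapply(readLines(path), jsonlite::fromJSON)
  d <- do.call(rbind, lapply(rows, as.data.frame))
  s <- jsonlite::read_json(paste0(path, ".summary.json"))
  new("FeedbackLog", subject = s$subject, day = s$day,
      runIndex = as.integer(s$run_index), decisions = d,
      piecesRevealed = as.integer(s$pieces_revealed),
      boardsCompleted = as.integer(s$boards_completed),
      boardSize = as.integer(s$board_size))
}

#' Write / read a study configuration as YAML
#'
#' @param config a study configuration list (see [studyConfig()]).
#' @param path YAML file path.
#' @return `writeStudyConfig()` returns `path` invisibly;
#'   `readStudyConfig()` returns the configuration list.
#' @export
writeStudyConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeStudyConfig
#' @export
readStudyConfig <- function(path) {
  yaml::read_yaml(path)
}
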