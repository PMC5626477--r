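# Shared fixtures and independent oracles, built in code at test time.

# Single-day spec with a flat (identity by default) correlation structure.
quickSpec <- function(nSubjects = 1L, nTR = 100L, t1t2 = 0, t1c = 0, t2c = 0,
                      arCoeff = 0, driftAmplitude = 0, seed = 1L,
                      feedback = 1L, restPre = 0L, restPost = 0L,
                      days = "day1", repairPsd = FALSE) {
  deltas <- matrix(0, length(days), 3,
                   dimnames = list(days, c("t1t2", "t1c", "t2c")))
  CohortSpec(nSubjects = nSubjects, days = days,
             runsPerDay = c(rest_pre = restPre, feedback = feedback,
                            rest_post = restPost),
             nTR = nTR, baselineCorr = corrMatrix3(t1t2, t1c, t2c),
             dayDeltas = deltas, arCoeff = arCoeff,
             driftAmplitude = driftAmplitude, seed = seed,
             repairPsd = repairPsd)
}

# Spec programming a day1 -> day4 change on the three pairs.
changeSpec <- function(nSubjects = 17L, nTR = 270L, seed = 1L,
                       baseline = c(0.1, 0.25, 0.1),
                       delta = c(0.1, -0.1, -0.1),
                       feedback = 4L, arCoeff = 0.3, driftAmplitude = 0.2) {
  days <- c("day1", "day4")
  deltas <- rbind(day1 = c(0, 0, 0), day4 = delta)
  colnames(deltas) <- c("t1t2", "t1c", "t2c")
  CohortSpec(nSubjects = nSubjects, days = days,
             runsPerDay = c(rest_pre = 0L, feedback = feedback, rest_post = 0L),
             nTR = nTR,
             baselineCorr = corrMatrix3(baseline[1], baseline[2], baseline[3]),
             dayDeltas = deltas, arCoeff = arCoeff,
             driftAmplitude = driftAmplitude, seed = seed)
}

# Independent vectorised oracle for the two-point rule: sign enumeration
# over the increment triples of a series matrix.
oracleFired <- function(series) {
  d <- diff(series)
  s <- sign(d)
  s[, 1] != 0 & s[, 1] == s[, 2] & s[, 3] == -s[, 1]
}

# Build a SubjectDaySummary table directly from per-subject values.
summariesFromValues <- function(valuesByDay, measure = "composite",
                                scope = "feedback_all") {
  do.call(rbind, lapply(names(valuesByDay), function(day) {
    v <- valuesByDay[[day]]
    out <- data.frame(subject = names(v), day = day, scope = scope,
                      stringsAsFactors = FALSE)
    out[[measure]] <- unname(v)
    out
  }))
}

# Exhaustive sign-flip permutation p-value (two-tailed, add-one smoothed
# against the full enumeration, so p = (#{|mean| >= |obs|}) / 2^n).
exhaustiveSignFlipP <- function(changes) {
  n <- length(changes)
  stopifnot(n <= 16)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  nullMeans <- as.numeric(signs %*% changes) / n
  mean(abs(nullMeans) >= abs(mean(changes)))
}

# Flood-fill oracle for 6-connected components (max cluster size).
oracleMaxCluster <- function(mask) {
  dims <- dim(mask)
  visited <- array(FALSE, dims)
  best <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (visited[start]) next
    queue <- start
    visited[start] <- TRUE
    size <- 0L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      size <- size + 1L
      co <- arrayInd(v, dims)
      for (axis in 1:3) for (dlt in c(-1L, 1L)) {
        nb <- co
        nb[axis] <- nb[axis] + dlt
        if (nb[axis] < 1L || nb[axis] > dims[axis]) next
        w <- nb[1] + dims[1] * (nb[2] - 1L) + dims[1] * dims[2] * (nb[3] - 1L)
        if (mask[w] && !visited[w]) {
          visited[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    best <- max(best, size)
  }
  best
}

# Tiny VoxelRun built from an explicit voxels x time matrix.
voxelRunFromMatrix <- function(data, gridShape, subject = "sub01",
                               day = "day1", runIndex = 1L,
                               runType = "feedback") {
  new("VoxelRun", subject = subject, day = day,
      runIndex = as.integer(runIndex), runType = runType,
      data = data, gridShape = as.integer(gridShape))
}
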