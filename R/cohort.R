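#' Construct a CohortSpec
#'
#' Builds the design object for one arm of a simulated covert-neurofeedback
#' study. Defaults reproduce the study conditions: 17 ASD-like subjects (10
#' for TD-like), four training days plus a follow-up, 2 pre-rest + 4
#' feedback + 2 post-rest runs per day, 270 samples per run at TR = 2 s.
#'
#' The day-1 correlation structure and its programmed trajectory default,
#' for the ASD-like arm, to a weakly connected target pair
#' (r(target1, target2) = 0.10) that is over-coupled to the control region
#' (r(target1, control) = 0.25), trained towards day-4 deltas of
#' (+0.11, -0.13, -0.03) on (t1t2, t1c, t2c) — a composite-measure change
#' of 0.19 — ramping over days as 0, 0.4, 0.75, 1 with 90% retention at
#' follow-up. The TD-like arm starts well connected
#' (r(target1, target2) = 0.5, target-control near 0) and is programmed
#' with no change on these pairs.
#'
#' @param nSubjects number of subjects (default 17 ASD-like, 10 TD-like).
#' @param groupLabel `"ASD-like"` (default) or `"TD-like"`.
#' @param days ordered day labels.
#' @param runsPerDay named counts `rest_pre`, `feedback`, `rest_post`.
#' @param nTR samples per run.
#' @param trSeconds sampling interval (s).
#' @param baselineCorr 3x3 day-1 inter-ROI correlation matrix; see
#'   [corrMatrix3()].
#' @param dayDeltas matrix (days x 3, columns `t1t2`, `t1c`, `t2c`) of
#'   additive correlation changes relative to baseline.
#' @param arCoeff shared AR(1) coefficient of the generated signals.
#' @param driftAmplitude slow-drift amplitude relative to unit signal SD.
#' @param noiseSd innovation SD.
#' @param seed integer RNG seed.
#' @param repairPsd repair non-PSD requested matrices by eigenvalue
#'   clipping instead of rejecting them.
#' @return a [CohortSpec-class] object.
#' @examples
#' spec <- CohortSpec(nSubjects = 3, seed = 1)
#' spec
#' @export
CohortSpec <- function(nSubjects = if (groupLabel == "ASD-like") 17L else 10L,
                       groupLabel = c("ASD-like", "TD-like"),
                       days = c("day1", "day2", "day3", "day4", "followup"),
                       runsPerDay = c(rest_pre = 2L, feedback = 4L, rest_post = 2L),
                       nTR = 270L,
                       trSeconds = 2,
                       baselineCorr = defaultBaselineCorr(groupLabel),
                       dayDeltas = defaultDayDeltas(days, groupLabel),
                       arCoeff = 0.3,
                       driftAmplitude = 0.2,
                       noiseSd = 1,
                       seed = 1L,
                       repairPsd = FALSE) {
  groupLabel <- match.arg(groupLabel)
  new("CohortSpec",
      nSubjects = as.integer(nSubjects), groupLabel = groupLabel,
      days = as.character(days),
      runsPerDay = stats::setNames(as.integer(runsPerDay), names(runsPerDay)),
      nTR = as.integer(nTR), trSeconds = as.numeric(trSeconds),
      baselineCorr = baselineCorr, dayDeltas = dayDeltas,
      arCoeff = as.numeric(arCoeff),
      driftAmplitude = as.numeric(driftAmplitude),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed),
      repairPsd = isTRUE(repairPsd))
}

#' @rdname CohortSpec
#' @export
defaultBaselineCorr <- function(groupLabel = c("ASD-like", "TD-like")) {
  groupLabel <- match.arg(groupLabel)
  if (groupLabel == "ASD-like") corrMatrix3(0.10, 0.25, 0.10)
  else corrMatrix3(0.50, 0.05, 0.05)
}

#' @rdname CohortSpec
#' @export
defaultDayDeltas <- function(days = c("day1", "day2", "day3", "day4", "followup"),
                             groupLabel = c("ASD-like", "TD-like")) {
  groupLabel <- match.arg(groupLabel)
  total <- if (groupLabel == "ASD-like") c(t1t2 = 0.11, t1c = -0.13, t2c = -0.03)
           else c(t1t2 = 0, t1c = 0, t2c = 0)
  frac <- dayRampFractions(days)
  d <- outer(frac, total)
  dimnames(d) <- list(days, PAIR_NAMES)
  d
}

# Learning ramp: known labels get the canonical fractions; otherwise a
# linear 0..1 ramp across the supplied days.
dayRampFractions <- function(days) {
  canonical <- c(day1 = 0, day2 = 0.4, day3 = 0.75, day4 = 1, followup = 0.9)
  if (all(days %in% names(canonical))) unname(canonical[days])
  else if (length(days) == 1L) 0
  else seq(0, 1, length.out = length(days))
}

# Per-day target correlation matrix implied by a CohortSpec.
dayCorrMatrix <- function(spec, day) {
  i <- match(day, spec@days)
  if (is.na(i)) stop("unknown day: ", day)
  d <- spec@dayDeltas[i, ]
  m <- spec@baselineCorr
  m[1, 2] <- m[2, 1] <- m[1, 2] + d[["t1t2"]]
  m[1, 3] <- m[3, 1] <- m[1, 3] + d[["t1c"]]
  m[2, 3] <- m[3, 2] <- m[2, 3] + d[["t2c"]]
  m
}

# Symmetric matrix square root (tolerates semidefinite input).
matrixSqrt <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# Simulate n x p series: correlated Gaussian innovations, shared-AR(1)
# filtering (stationary init), rescaled to unit variance, plus optional
# per-column sinusoidal drift. Consumes the current RNG stream.
simulateCorrelatedSeries <- function(n, corr, arCoeff = 0, driftAmplitude = 0,
                                     noiseSd = 1) {
  p <- ncol(corr)
  L <- matrixSqrt(corr)
  e <- matrix(stats::rnorm(n * p, sd = noiseSd), n, p) %*% L
  if (arCoeff > 0) {
    statSd <- noiseSd / sqrt(1 - arCoeff^2)
    init <- as.numeric(L %*% stats::rnorm(p, sd = statSd))
    x <- vapply(seq_len(p), function(j)
      as.numeric(stats::filter(e[, j], arCoeff, method = "recursive",
                               init = init[j])), numeric(n))
    x <- x / statSd
  } else {
    x <- e / noiseSd
  }
  if (driftAmplitude > 0) {
    for (j in seq_len(p)) {
      f <- stats::runif(1, 0.5, 2)
      phi <- stats::runif(1, 0, 2 * pi)
      x[, j] <- x[, j] + driftAmplitude * sin(2 * pi * f * seq_len(n) / n + phi)
    }
  }
  colnames(x) <- colnames(corr)
  x
}

# Resolve (check/repair) every day's correlation matrix for a spec.
# Returns list(matrices = named list, repaired = character vector of days).
resolveDayMatrices <- function(spec) {
  out <- list()
  repaired <- character()
  for (day in spec@days) {
    m <- dayCorrMatrix(spec, day)
    if (any(abs(m) > 1 + 1e-12))
      stop("programmed correlations for ", day, " fall outside [-1, 1]")
    if (!isPSD(m)) {
      if (!spec@repairPsd)
        stop("requested correlation matrix for ", day,
             " is not positive semidefinite; set repairPsd = TRUE to repair")
      m <- nearestPSD(m)
      repaired <- c(repaired, day)
    }
    out[[day]] <- m
  }
  list(matrices = out, repaired = repaired)
}

#' Construct a single RoiRun
#'
#' @param series numeric matrix, nTR x 3, columns target1/target2/control
#'   (column names are set if missing).
#' @param subject,day,runIndex,runType run identity metadata.
#' @return a [RoiRun-class] object.
#' @examples
#' RoiRun(matrix(rnorm(30), 10, 3))
#' @export
RoiRun <- function(series, subject = "sub01", day = "day1", runIndex = 1L,
                   runType = c("rest", "feedback")) {
  runType <- match.arg(runType)
  series <- as.matrix(series)
  colnames(series) <- ROI_NAMES
  new("RoiRun", subject = subject, day = day, runIndex = as.integer(runIndex),
      runType = runType, series = series)
}

#' Generate a synthetic ROI-level cohort
#'
#' Simulates, for every subject, day and run of the design, a three-ROI
#' BOLD-like time series whose inter-ROI correlations follow the day's
#' programmed correlation matrix. Signals are latent multivariate Gaussian
#' innovations passed through a shared AR(1) filter (which preserves the
#' innovation correlations), rescaled to unit variance, with additive
#' slow sinusoidal drift per ROI. Regenerating with the same spec yields
#' bit-identical output.
#'
#' @param spec a [CohortSpec-class].
#' @return a named list of [RoiRun-class] objects
#'   (`subject.day.runNN`), with attributes `repairedDays` (days whose
#'   requested correlation matrix was PSD-repaired) and `spec`.
#' @examples
#' runs <- generateRoiCohort(CohortSpec(nSubjects = 1, days = "day1",
#'   runsPerDay = c(rest_pre = 0L, feedback = 1L, rest_post = 0L),
#'   nTR = 50L, seed = 7))
#' runs[[1]]
#' @export
generateRoiCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  resolved <- resolveDayMatrices(spec)
  subjects <- sprintf("sub%02d", seq_len(spec@nSubjects))
  rpd <- spec@runsPerDay
  types <- c(rep("rest", rpd[["rest_pre"]]), rep("feedback", rpd[["feedback"]]),
             rep("rest", rpd[["rest_post"]]))
  runs <- withSeed(spec@seed, {
    out <- list()
    for (subj in subjects) {
      for (day in spec@days) {
        m <- resolved$matrices[[day]]
        for (i in seq_along(types)) {
          series <- simulateCorrelatedSeries(
            spec@nTR, m, spec@arCoeff, spec@driftAmplitude, spec@noiseSd)
          out[[paste(subj, day, sprintf("run%02d", i), sep = ".")]] <-
            RoiRun(series, subject = subj, day = day, runIndex = i,
                   runType = types[i])
        }
      }
    }
    out
  })
  attr(runs, "repairedDays") <- resolved$repaired
  attr(runs, "spec") <- spec
  runs
}

#' Generate synthetic behavioral change scores tied to connectivity change
#'
#' Emulates the study's parent-report scales: per-subject SRS change
#' (pre minus post, positive = symptom reduction) is a programmed linear
#' function of that subject's connectivity change plus noise, while BRIEF
#' change is pure noise (no programmed linkage). Optionally injects
#' extreme-change subjects guaranteed to exceed 3 SD of a reference
#' test-retest change distribution; following the study's observed
#' outliers, injected changes are large and negative.
#'
#' @param connectivityChange named numeric vector, one composite-measure
#'   change per subject.
#' @param slope programmed linear dependence of SRS change on connectivity
#'   change (scale points per unit correlation change).
#' @param noiseSd SD of the additive noise on SRS change.
#' @param nOutliers number of injected outlier subjects (the last
#'   `nOutliers` subjects are replaced).
#' @param referenceChanges reference test-retest change sample used to
#'   place the injected outliers beyond 3 SD.
#' @param seed RNG seed.
#' @return a `BehaviorTable` data.frame with columns `subject`, `srs_pre`,
#'   `srs_post`, `srs_change`, `brief_pre`, `brief_post`, `brief_change`,
#'   `injected_outlier`.
#' @seealso [generateReferenceChanges()], [flagOutliers()]
#' @export
generateBehavior <- function(connectivityChange, slope = 30, noiseSd = 4,
                             nOutliers = 0L,
                             referenceChanges = generateReferenceChanges(seed = seed + 1L),
                             seed = 1L) {
  n <- length(connectivityChange)
  subjects <- names(connectivityChange)
  if (is.null(subjects)) subjects <- sprintf("sub%02d", seq_len(n))
  if (nOutliers > n) stop("nOutliers exceeds the number of subjects")
  withSeed(seed, {
    srs_change <- slope * as.numeric(connectivityChange) +
      stats::rnorm(n, sd = noiseSd)
    injected <- rep(FALSE, n)
    if (nOutliers > 0L) {
      mu <- mean(referenceChanges)
      s <- stats::sd(referenceChanges)
      idx <- seq.int(n - nOutliers + 1L, n)
      srs_change[idx] <- mu - (3.5 + stats::runif(nOutliers)) * s
      injected[idx] <- TRUE
    }
    srs_pre <- stats::rnorm(n, mean = 69.8, sd = 8)
    brief_pre <- stats::rnorm(n, mean = 60, sd = 8)
    brief_change <- stats::rnorm(n, sd = noiseSd)
    data.frame(
      subject = subjects,
      srs_pre = srs_pre, srs_post = srs_pre - srs_change,
      srs_change = srs_change,
      brief_pre = brief_pre, brief_post = brief_pre - brief_change,
      brief_change = brief_change,
      injected_outlier = injected,
      stringsAsFactors = FALSE)
  })
}

#' Generate a reference test-retest change distribution
#'
#' Stand-in for an independent test-retest dataset of scale changes, used
#' to calibrate the 3-SD outlier rule. Synthetic: plain Gaussian changes.
#'
#' @param n sample size.
#' @param mean,sd distribution of the reference changes.
#' @param seed RNG seed.
#' @return numeric vector of reference changes.
#' @export
generateReferenceChanges <- function(n = 40L, mean = 0, sd = 5, seed = 1L) {
  withSeed(seed, stats::rnorm(n, mean, sd))
}
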