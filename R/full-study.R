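#' Default full-study configuration
#'
#' Assembles the configuration for [runFullStudy()]: the two cohort arms
#' (an ASD-like arm trained towards network differentiation and a
#' TD-like arm receiving orthogonal training, i.e. no programmed change
#' on the trained pairs), analysis parameters, and the seeds of every
#' stochastic stage. All seeds derive from `seed`, so a config is fully
#' reproducible from one integer.
#'
#' @param seed master seed.
#' @param nSubjectsAsd,nSubjectsTd arm sizes (study values 17 and 10).
#' @param nTR samples per run.
#' @param nIterations permutation iterations for the learning contrasts.
#' @param behaviorSlope,behaviorNoiseSd,nOutliers synthetic behaviour
#'   linkage parameters (see [generateBehavior()]).
#' @param contrast the contrasted day pair.
#' @return a named configuration list.
#' @export
studyConfig <- function(seed = 1L, nSubjectsAsd = 17L, nSubjectsTd = 10L,
                        nTR = 270L, nIterations = 5000L,
                        behaviorSlope = 30, behaviorNoiseSd = 4,
                        nOutliers = 0L, contrast = c("day1", "day4")) {
  list(
    seed = as.integer(seed),
    arms = list(
      asd = list(nSubjects = as.integer(nSubjectsAsd),
                 groupLabel = "ASD-like", seed = childSeed(seed, "asd")),
      td = list(nSubjects = as.integer(nSubjectsTd),
                groupLabel = "TD-like", seed = childSeed(seed, "td"))),
    nTR = as.integer(nTR),
    nIterations = as.integer(nIterations),
    contrast = contrast,
    behavior = list(slope = behaviorSlope, noiseSd = behaviorNoiseSd,
                    nOutliers = as.integer(nOutliers),
                    seed = childSeed(seed, "behavior")),
    analysisSeed = childSeed(seed, "analysis"))
}

# Per-subject change between two summaries tables / scopes.
scopedChange <- function(records, scopeA, scopeB, dayA, dayB, measure) {
  sa <- aggregateByDay(records, scopeA)
  sb <- aggregateByDay(records, scopeB)
  a <- sa[sa$day == dayA, c("subject", measure)]
  b <- sb[sb$day == dayB, c("subject", measure)]
  merged <- merge(a, b, by = "subject", suffixes = c("_a", "_b"))
  stats::setNames(merged[[paste0(measure, "_b")]] - merged[[paste0(measure, "_a")]],
                  merged$subject)
}

# One arm's pipeline: cohort -> feedback logs -> records -> contrasts.
runArm <- function(armCfg, config) {
  spec <- CohortSpec(nSubjects = armCfg$nSubjects,
                     groupLabel = armCfg$groupLabel,
                     nTR = config$nTR, seed = armCfg$seed)
  runs <- generateRoiCohort(spec)
  fbRuns <- Filter(function(r) r@runType == "feedback", runs)
  logs <- lapply(fbRuns, runFeedbackSession)
  records <- connectivityRecords(runs)
  summaries <- aggregateByDay(records, "feedback_all")
  contrast <- dayContrastPermutation(
    summaries, config$contrast[1], config$contrast[2],
    measure = "composite", nIterations = config$nIterations,
    seed = childSeed(config$analysisSeed, armCfg$groupLabel, "contrast"))
  restSummaries <- aggregateByDay(records, "rest_pre")
  restContrast <- dayContrastPermutation(
    restSummaries, config$contrast[1], config$contrast[2],
    measure = "composite", nIterations = config$nIterations,
    seed = childSeed(config$analysisSeed, armCfg$groupLabel, "rest"))
  list(spec = spec, runs = runs, logs = logs, records = records,
       summaries = summaries, contrast = contrast,
       restContrast = restContrast,
       firedFractions = vapply(logs, firedFraction, numeric(1)))
}

#' Run the full synthetic study
#'
#' End-to-end pipeline on synthetic data: generates both cohort arms,
#' runs the streaming feedback engine over every feedback run, computes
#' connectivity records and day-level summaries, tests the day1-to-day4
#' learning contrast (feedback and pre-feedback rest scopes) in each
#' arm, tests the group interaction (Welch), derives per-subject
#' resting-state change (post-training rest on the last day minus
#' pre-training rest on the first), generates linked behaviour scores,
#' flags outliers against a synthetic reference test-retest sample, and
#' runs the brain-behaviour correlation and partial correlations.
#' Running twice with the same configuration yields identical reports.
#'
#' @param config configuration list from [studyConfig()] (or read with
#'   [readStudyConfig()]).
#' @param outDir optional directory; when given, a JSON report and a
#'   markdown summary are written there.
#' @return the report: a nested list with elements `provenance`, `asd`,
#'   `td` (each arm's contrasts and mean fired fraction),
#'   `interaction`, `behavior`.
#' @export
runFullStudy <- function(config = studyConfig(), outDir = NULL) {
  asd <- runArm(config$arms$asd, config)
  td <- runArm(config$arms$td, config)
  interaction <- groupInteraction(asd$contrast$changes, td$contrast$changes)

  restChange <- scopedChange(asd$records, "rest_pre", "rest_post",
                             config$contrast[1], config$contrast[2],
                             "composite")
  behaviorTable <- generateBehavior(
    restChange, slope = config$behavior$slope,
    noiseSd = config$behavior$noiseSd,
    nOutliers = config$behavior$nOutliers,
    seed = config$behavior$seed)
  reference <- generateReferenceChanges(seed = childSeed(config$seed, "ref"))
  behaviorTable <- flagOutliers(behaviorTable, reference)
  bb <- brainBehaviorCorrelation(
    restChange, behaviorTable$srs_change,
    outlierFlags = behaviorTable$outlier_flag,
    nPermutations = config$nIterations,
    seed = childSeed(config$analysisSeed, "bb"))
  baselineRest <- aggregateByDay(asd$records, "rest_pre")
  baselineRest <- baselineRest[baselineRest$day == config$contrast[1], ]
  covariates <- cbind(baselineSrs = behaviorTable$srs_pre,
                      baselineRest = baselineRest$composite[
                        match(behaviorTable$subject, baselineRest$subject)])
  partial <- partialBrainBehavior(
    restChange, behaviorTable$srs_change, covariates,
    nPermutations = config$nIterations,
    seed = childSeed(config$analysisSeed, "partial"))
  partialBrief <- partialBrainBehavior(
    restChange, behaviorTable$srs_change,
    cbind(briefChange = behaviorTable$brief_change),
    nPermutations = config$nIterations,
    seed = childSeed(config$analysisSeed, "partial-brief"))

  armSummary <- function(arm) {
    list(nSubjects = arm$spec@nSubjects,
         groupLabel = arm$spec@groupLabel,
         seed = arm$spec@seed,
         meanFiredFraction = mean(arm$firedFractions),
         contrast = arm$contrast[c("dayA", "dayB", "measure", "meanChange",
                                   "p", "nIterations", "tail", "seed")],
         restContrast = arm$restContrast[c("meanChange", "p", "seed")])
  }
  report <- list(
    provenance = list(masterSeed = config$seed, nTR = config$nTR,
                      nIterations = config$nIterations,
                      contrast = config$contrast,
                      analysisSeed = config$analysisSeed),
    asd = armSummary(asd),
    td = armSummary(td),
    interaction = interaction,
    behavior = list(
      table = behaviorTable,
      correlation = bb,
      partialBaselines = partial[c("r", "p")],
      partialBrief = partialBrief[c("r", "p")]))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = 12, force = TRUE)
    writeLines(reportMarkdown(report), file.path(outDir, "report.md"))
  }
  report
}

# Human-readable summary of a full-study report.
reportMarkdown <- function(report) {
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "f")
  c("# Synthetic covert-neurofeedback study report",
    "",
    sprintf("Master seed: %d; %d TRs/run; %d permutation iterations.",
            report$provenance$masterSeed, report$provenance$nTR,
            report$provenance$nIterations),
    "",
    "## Learning (feedback runs, composite measure)",
    sprintf("- ASD-like arm (n = %d): mean %s -> %s change = %s, p = %s",
            report$asd$nSubjects, report$asd$contrast$dayA,
            report$asd$contrast$dayB, fmt(report$asd$contrast$meanChange),
            fmt(report$asd$contrast$p, 4)),
    sprintf("- TD-like arm (n = %d): mean change = %s, p = %s",
            report$td$nSubjects, fmt(report$td$contrast$meanChange),
            fmt(report$td$contrast$p, 4)),
    sprintf("- Group interaction (Welch): t = %s, df = %s, p = %s",
            fmt(report$interaction$t), fmt(report$interaction$df, 1),
            fmt(report$interaction$p, 4)),
    "",
    "## Transfer to rest (pre-feedback rest runs)",
    sprintf("- ASD-like arm: mean change = %s, p = %s",
            fmt(report$asd$restContrast$meanChange),
            fmt(report$asd$restContrast$p, 4)),
    "",
    "## Brain-behaviour",
    sprintf("- r (outliers excluded, n = %d) = %s, p = %s",
            report$behavior$correlation$excluding$n,
            fmt(report$behavior$correlation$excluding$r),
            fmt(report$behavior$correlation$excluding$p, 4)),
    sprintf("- r (outliers included, n = %d) = %s, p = %s",
            report$behavior$correlation$including$n,
            fmt(report$behavior$correlation$including$r),
            fmt(report$behavior$correlation$including$p, 4)),
    sprintf("- partial r (baseline SRS + baseline rest) = %s, p = %s",
            fmt(report$behavior$partialBaselines$r),
            fmt(report$behavior$partialBaselines$p, 4)))
}
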