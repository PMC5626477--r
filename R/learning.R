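#' Aggregate connectivity records to subject-by-day summaries
#'
#' Averages per-run connectivity over the runs matching a scope:
#' `feedback_all` (all feedback runs of the day), `feedback_first2` (the
#' first two feedback runs, used when comparing full days to the
#' two-run follow-up session), `rest_pre` (rest runs acquired before the
#' day's first feedback run — the uncontaminated baseline) or
#' `rest_post` (rest runs after the last feedback run).
#'
#' @param records `ConnectivityRecord` data.frame from
#'   [connectivityRecords()].
#' @param scope one of `"feedback_all"`, `"feedback_first2"`,
#'   `"rest_pre"`, `"rest_post"`.
#' @return a `SubjectDaySummary` data.frame: `subject`, `day`, `scope`,
#'   and the means of `r_t1t2`, `r_t1c`, `r_t2c`, `z_t1t2`, `z_t1c`,
#'   `z_t2c`, `composite` over the matching runs.
#' @export
aggregateByDay <- function(records,
                           scope = c("feedback_all", "feedback_first2",
                                     "rest_pre", "rest_post")) {
  scope <- match.arg(scope)
  measures <- c("r_t1t2", "r_t1c", "r_t2c", "z_t1t2", "z_t1c", "z_t2c",
                "composite")
  groups <- split(records, list(records$subject, records$day), drop = TRUE)
  rows <- lapply(groups, function(g) {
    fb <- g[g$run_type == "feedback", , drop = FALSE]
    sel <- switch(scope,
      feedback_all = fb,
      feedback_first2 = utils::head(fb[order(fb$run_index), , drop = FALSE], 2L),
      rest_pre = g[g$run_type == "rest" &
                   (nrow(fb) == 0L | g$run_index < suppressWarnings(min(fb$run_index))), ,
                   drop = FALSE],
      rest_post = g[g$run_type == "rest" & nrow(fb) > 0L &
                    g$run_index > max(fb$run_index), , drop = FALSE])
    if (nrow(sel) == 0L) return(NULL)
    out <- data.frame(subject = g$subject[1], day = g$day[1], scope = scope,
                      stringsAsFactors = FALSE)
    for (m in measures) out[[m]] <- mean(sel[[m]])
    out
  })
  missing <- names(rows)[vapply(rows, is.null, logical(1))]
  if (length(missing))
    stop("no runs in scope '", scope, "' for (subject, day): ",
         paste(missing, collapse = "; "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Paired per-subject changes day_b - day_a for one measure.
pairedChanges <- function(summaries, dayA, dayB, measure) {
  a <- summaries[summaries$day == dayA, c("subject", measure)]
  b <- summaries[summaries$day == dayB, c("subject", measure)]
  merged <- merge(a, b, by = "subject", suffixes = c("_a", "_b"))
  absent <- setdiff(union(a$subject, b$subject), merged$subject)
  if (length(absent))
    stop("subjects missing one of the contrasted days: ",
         paste(absent, collapse = ", "))
  if (nrow(merged) == 0L) stop("no paired subjects for ", dayA, " vs ", dayB)
  stats::setNames(merged[[paste0(measure, "_b")]] - merged[[paste0(measure, "_a")]],
                  merged$subject)
}

#' Paired day-contrast permutation test
#'
#' Tests whether a connectivity measure changed between two days. The
#' observed statistic is the mean within-subject change (`dayB - dayA`);
#' the null distribution is built by independently permuting each
#' subject's two day labels — equivalently, flipping the sign of each
#' subject's change — for `nIterations` iterations. The p-value uses
#' add-one smoothing, so its floor is `1 / (nIterations + 1)`;
#' the default convention is two-tailed.
#'
#' @param summaries `SubjectDaySummary` data.frame from
#'   [aggregateByDay()].
#' @param dayA,dayB day labels to contrast (change reported as
#'   `dayB - dayA`).
#' @param measure summary column to test (default `"composite"`).
#' @param nIterations permutation iterations (default 5000; at least
#'   100).
#' @param seed RNG seed.
#' @param tail `"two"` (default) or `"one"` (upper tail: change > 0).
#' @return a `DayContrastResult` list: `dayA`, `dayB`, `measure`,
#'   `meanChange`, `p`, `nIterations`, `tail`, `seed`, `changes`
#'   (named per-subject changes).
#' @export
dayContrastPermutation <- function(summaries, dayA, dayB,
                                   measure = "composite",
                                   nIterations = 5000L, seed = 1L,
                                   tail = c("two", "one")) {
  tail <- match.arg(tail)
  nIterations <- as.integer(nIterations)
  if (nIterations < 100L) stop("nIterations must be at least 100")
  changes <- pairedChanges(summaries, dayA, dayB, measure)
  n <- length(changes)
  obs <- mean(changes)
  nullMeans <- withSeed(seed, {
    signs <- matrix(sample(c(-1, 1), nIterations * n, replace = TRUE),
                    nIterations, n)
    as.numeric(signs %*% changes) / n
  })
  list(dayA = dayA, dayB = dayB, measure = measure,
       meanChange = obs,
       p = permPValue(nullMeans, obs, twoTailed = tail == "two"),
       nIterations = nIterations, tail = tail, seed = as.integer(seed),
       changes = changes)
}

#' Robustness of a day contrast over all subsets of participants
#'
#' Re-computes the mean change and its sign-flip permutation p-value for
#' every subset of `subsetSize` subjects, mirroring the study's check
#' that the day1-to-day4 effect was not carried by a few participants.
#' One sign-flip matrix (independent of the data) is shared across
#' subsets, which keeps the enumeration vectorised; each subset's
#' p-value is a valid permutation p.
#'
#' @inheritParams dayContrastPermutation
#' @param subsetSize subjects per subset (default 10).
#' @param alpha significance level for the summary fraction.
#' @param maxSubsets refuse to enumerate more than this many subsets
#'   unless `sampleSubsets` is set.
#' @param sampleSubsets if not `NULL`, sample this many random subsets
#'   instead of enumerating.
#' @return a list: `nSubsets`, `meanChanges`, `pValues`,
#'   `rangeMeanChange`, `fractionSignificant` (at `alpha`), `alpha`,
#'   `subsetSize`.
#' @export
subsetRobustness <- function(summaries, subsetSize = 10L, dayA, dayB,
                             measure = "composite", nIterations = 1000L,
                             alpha = 0.05, seed = 1L, maxSubsets = 1e6,
                             sampleSubsets = NULL) {
  changes <- pairedChanges(summaries, dayA, dayB, measure)
  n <- length(changes)
  k <- as.integer(subsetSize)
  if (n < k) stop("need at least subsetSize subjects")
  nAll <- choose(n, k)
  if (is.null(sampleSubsets)) {
    if (nAll > maxSubsets)
      stop("choose(", n, ", ", k, ") = ", nAll, " subsets; pass sampleSubsets ",
           "to sample instead of enumerating")
    subsets <- utils::combn(n, k)
  } else {
    subsets <- withSeed(childSeed(seed, "subsets"),
      vapply(seq_len(sampleSubsets), function(i) sort(sample(n, k)),
             integer(k)))
  }
  nSub <- ncol(subsets)
  chMat <- matrix(changes[subsets], k, nSub)
  means <- colMeans(chMat)
  signs <- withSeed(seed,
    matrix(sample(c(-1, 1), nIterations * k, replace = TRUE), nIterations, k))
  pValues <- numeric(nSub)
  block <- 4000L
  for (start in seq(1L, nSub, by = block)) {
    idx <- start:min(start + block - 1L, nSub)
    nullMeans <- (signs %*% chMat[, idx, drop = FALSE]) / k
    exceed <- colSums(abs(nullMeans) >= rep(abs(means[idx]),
                                            each = nrow(nullMeans)))
    pValues[idx] <- (1 + exceed) / (nIterations + 1)
  }
  list(nSubsets = nSub, meanChanges = means, pValues = pValues,
       rangeMeanChange = range(means),
       fractionSignificant = mean(pValues < alpha),
       alpha = alpha, subsetSize = k)
}

#' Group interaction: Welch two-sample t-test on change scores
#'
#' Compares the per-subject changes of two groups (e.g. ASD-like vs
#' TD-like arms) without assuming equal variances, to control for the
#' different sample sizes: Welch's t statistic with
#' Welch-Satterthwaite degrees of freedom and a two-tailed p. When both
#' groups have zero variance and equal means the result is `t = 0`,
#' `p = 1` by convention.
#'
#' @param changesGroup1,changesGroup2 numeric vectors (each n >= 2).
#' @return a list: `t`, `df`, `p`, `meanDiff` (group1 - group2).
#' @examples
#' groupInteraction(c(1, 2, 3), c(4, 5, 6))
#' @export
groupInteraction <- function(changesGroup1, changesGroup2) {
  if (length(changesGroup1) < 2L || length(changesGroup2) < 2L)
    stop("each group needs at least 2 observations")
  v1 <- stats::var(changesGroup1)
  v2 <- stats::var(changesGroup2)
  diff <- mean(changesGroup1) - mean(changesGroup2)
  if (v1 == 0 && v2 == 0) {
    if (diff == 0) return(list(t = 0, df = NA_real_, p = 1, meanDiff = 0))
    return(list(t = sign(diff) * Inf, df = NA_real_, p = 0, meanDiff = diff))
  }
  ht <- stats::t.test(changesGroup1, changesGroup2, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, meanDiff = diff)
}

#' Retention of learning versus elapsed time
#'
#' For each subject, the retention fraction is
#' `(followup - day1) / (day4 - day1)` on the chosen measure (1 = full
#' maintenance of the trained change). The function correlates retention
#' with the weeks elapsed since training, with a permutation p-value
#' obtained by shuffling the elapsed times. Subjects with a zero
#' day4 - day1 change have no defined retention and are excluded with a
#' warning.
#'
#' @param summaries `SubjectDaySummary` data.frame containing `day1`,
#'   `day4` and the follow-up day.
#' @param elapsedWeeks named numeric vector (names = subjects) of weeks
#'   between the last training day and follow-up.
#' @param measure summary column (default `"composite"`).
#' @param day1,day4,followup day labels.
#' @param nPermutations,seed permutation settings.
#' @return a list: `retention` (named per-subject fractions), `r`
#'   (Pearson correlation with elapsed time; `NA` with
#'   `degenerate = TRUE` when retention has zero variance), `p`,
#'   `nExcluded`.
#' @export
retentionAnalysis <- function(summaries, elapsedWeeks, measure = "composite",
                              day1 = "day1", day4 = "day4",
                              followup = "followup",
                              nPermutations = 5000L, seed = 1L) {
  trained <- pairedChanges(summaries, day1, day4, measure)
  kept <- pairedChanges(summaries, day1, followup, measure)
  common <- intersect(names(trained), names(kept))
  common <- intersect(common, names(elapsedWeeks))
  if (length(common) == 0L) stop("no subjects with follow-up summaries and elapsed times")
  trained <- trained[common]
  kept <- kept[common]
  zero <- trained == 0
  if (any(zero))
    warning(sum(zero), " subject(s) excluded: zero day4 - day1 change")
  retention <- kept[!zero] / trained[!zero]
  weeks <- elapsedWeeks[names(retention)]
  if (length(retention) < 3L)
    stop("fewer than 3 subjects with defined retention")
  if (stats::sd(retention) == 0 || stats::sd(weeks) == 0) {
    return(list(retention = retention, r = NA_real_, p = NA_real_,
                nExcluded = sum(zero), degenerate = TRUE))
  }
  r <- stats::cor(retention, weeks)
  nullStats <- withSeed(seed, vapply(seq_len(nPermutations), function(i)
    stats::cor(retention, sample(weeks)), numeric(1)))
  list(retention = retention, r = r, p = permPValue(nullStats, r),
       nExcluded = sum(zero), degenerate = FALSE)
}
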