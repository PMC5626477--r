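#' Flag behavioural change-score outliers against a reference distribution
#'
#' Flags subjects whose change score lies beyond
#' `mean(reference) +/- multiplier * sd(reference)`, where the reference
#' is an independent test-retest change sample (the study used an
#' independent ASD test-retest dataset; [generateReferenceChanges()]
#' provides a synthetic stand-in). The default multiplier is 3.
#'
#' @param table `BehaviorTable` data.frame (from [generateBehavior()] or
#'   user data) with the change column named by `column`.
#' @param referenceChanges numeric reference sample, n >= 10.
#' @param multiplier SD multiplier (default 3).
#' @param column change column to screen (default `"srs_change"`).
#' @return the table with logical column `outlier_flag` and character
#'   column `outlier_reason` added.
#' @export
flagOutliers <- function(table, referenceChanges, multiplier = 3,
                         column = "srs_change") {
  if (length(referenceChanges) < 10L)
    stop("reference sample must have at least 10 observations")
  s <- stats::sd(referenceChanges)
  if (s == 0) stop("reference sample has zero standard deviation")
  m <- mean(referenceChanges)
  lo <- m - multiplier * s
  hi <- m + multiplier * s
  x <- table[[column]]
  flag <- x < lo | x > hi
  table$outlier_flag <- flag
  table$outlier_reason <- ifelse(
    flag, sprintf("%s = %.2f outside [%.2f, %.2f]", column, x, lo, hi), "")
  table
}

#' Pearson correlation with a seeded label-permutation p-value
#'
#' The permutation engine shared by the proxy validation, retention and
#' brain-behaviour analyses: the observed Pearson correlation is compared
#' (two-tailed, add-one smoothing) against the correlations obtained by
#' randomly re-pairing `y` against `x`.
#'
#' @param x,y paired numeric vectors.
#' @param nPermutations number of random re-pairings.
#' @param seed RNG seed.
#' @return a list: `r`, `p`, `degenerate` (`TRUE`, with `NA` values,
#'   when either input has zero variance).
#' @export
permutationCorTest <- function(x, y, nPermutations = 5000L, seed = 1L) {
  permCorTest(x, y, nPermutations, seed)
}

permCorTest <- function(x, y, nPermutations, seed) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, degenerate = TRUE))
  r <- stats::cor(x, y)
  nullStats <- withSeed(seed, vapply(seq_len(nPermutations), function(i)
    stats::cor(x, sample(y)), numeric(1)))
  list(r = r, p = permPValue(nullStats, r), degenerate = FALSE)
}

#' Brain-behaviour correlation with permutation inference
#'
#' Correlates per-subject connectivity change with behavioural change
#' (Pearson r, subject-label permutation p-value) both with and without
#' the flagged outliers, reporting both — mirroring the study's practice
#' of also running the analysis with the outliers included.
#'
#' @param connectivityChanges named numeric vector of per-subject
#'   connectivity (composite) changes.
#' @param behaviorChanges named numeric vector of per-subject behavioural
#'   changes (pre minus post, positive = symptom reduction).
#' @param outlierFlags logical vector aligned with the subjects (default
#'   none flagged).
#' @param nPermutations permutation iterations (default 5000).
#' @param seed RNG seed.
#' @return a list with elements `excluding` and `including`, each a list
#'   `r`, `p`, `n`, `degenerate`; plus `nOutliers`.
#' @export
brainBehaviorCorrelation <- function(connectivityChanges, behaviorChanges,
                                     outlierFlags = rep(FALSE, length(behaviorChanges)),
                                     nPermutations = 5000L, seed = 1L) {
  stopifnot(length(connectivityChanges) == length(behaviorChanges),
            length(outlierFlags) == length(behaviorChanges))
  keep <- !outlierFlags
  if (sum(keep) < 5L) stop("fewer than 5 paired observations after exclusion")
  runOne <- function(sel, s) {
    res <- permCorTest(connectivityChanges[sel], behaviorChanges[sel],
                       nPermutations, s)
    res$n <- sum(sel)
    res
  }
  list(excluding = runOne(keep, seed),
       including = runOne(rep(TRUE, length(keep)), childSeed(seed, "incl")),
       nOutliers = sum(outlierFlags))
}

# Residuals of y on a covariate matrix (with intercept).
residualize <- function(y, covariates) {
  stats::lm.fit(cbind(1, covariates), y)$residuals
}

#' Partial brain-behaviour correlation
#'
#' Partial Pearson correlation between connectivity change and
#' behavioural change after removing the linear contribution of one or
#' more covariates (e.g. baseline behaviour score, baseline resting
#' connectivity, or the change on a control scale): both variables are
#' residualised on the covariates and the residuals correlated, with a
#' permutation p-value obtained by shuffling the behaviour residuals.
#' For a single covariate this equals the closed-form partial-correlation
#' identity `(rxy - rxz * ryz) / sqrt((1 - rxz^2) (1 - ryz^2))`.
#'
#' @param connectivityChanges,behaviorChanges numeric vectors as in
#'   [brainBehaviorCorrelation()].
#' @param covariates numeric vector or matrix (subjects x covariates),
#'   full column rank required.
#' @param nPermutations,seed permutation settings.
#' @return a list: `r` (partial correlation; `NA` with
#'   `degenerate = TRUE` if a residual has zero variance), `p`,
#'   `nCovariates`, `n`.
#' @export
partialBrainBehavior <- function(connectivityChanges, behaviorChanges,
                                 covariates, nPermutations = 5000L,
                                 seed = 1L) {
  covariates <- as.matrix(covariates)
  n <- length(connectivityChanges)
  stopifnot(length(behaviorChanges) == n, nrow(covariates) == n)
  if (n <= ncol(covariates) + 2L)
    stop("need more than #covariates + 2 observations")
  qrC <- qr(cbind(1, covariates))
  if (qrC$rank < ncol(covariates) + 1L) {
    keep <- qrC$pivot[seq_len(qrC$rank)]
    dropped <- setdiff(seq_len(ncol(covariates) + 1L), keep) - 1L
    stop("collinear covariate column(s): ", paste(dropped, collapse = ", "))
  }
  rx <- residualize(connectivityChanges, covariates)
  ry <- residualize(behaviorChanges, covariates)
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12)
    return(list(r = NA_real_, p = NA_real_, degenerate = TRUE,
                nCovariates = ncol(covariates), n = n))
  res <- permCorTest(rx, ry, nPermutations, seed)
  list(r = res$r, p = res$p, degenerate = FALSE,
       nCovariates = ncol(covariates), n = n)
}
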