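#' Fisher z-transform and its inverse
#'
#' `fisherZ()` is `atanh(r)`; `fisherZInv()` is `tanh(z)`. Used to
#' normalise correlations before averaging and t-tests in the voxelwise
#' analysis.
#'
#' @param r correlation value(s) in (-1, 1).
#' @param z Fisher-z value(s).
#' @return transformed value(s).
#' @examples
#' fisherZ(0.5)
#' fisherZInv(fisherZ(0.5))
#' @export
fisherZ <- function(r) atanh(r)

#' @rdname fisherZ
#' @export
fisherZInv <- function(z) tanh(z)

#' Composite difference measure
#'
#' The network-level summary trained by the feedback: the target-target
#' correlation minus the average of the two target-control correlations,
#' `r(t1, t2) - (r(t1, c) + r(t2, c)) / 2`. Larger values mean a more
#' differentiated (typically developing-like) network: coupled targets,
#' decoupled control.
#'
#' @param r_t1t2,r_t1c,r_t2c the three pairwise correlations, each between -1 and 1.
#' @return the composite value.
#' @examples
#' compositeMeasure(0.5, 0.2, 0.1)  # 0.35
#' @export
compositeMeasure <- function(r_t1t2, r_t1c, r_t2c) {
  stopifnot(all(abs(c(r_t1t2, r_t1c, r_t2c)) <= 1))
  r_t1t2 - (r_t1c + r_t2c) / 2
}

#' Pairwise connectivity of a run
#'
#' Computes the three pairwise Pearson correlations of a run's ROI
#' series, their Fisher-z transforms and the composite difference
#' measure.
#'
#' @param run a [RoiRun-class] with at least 3 samples and nonconstant
#'   series.
#' @return a one-row `ConnectivityRecord` data.frame with columns
#'   `subject`, `day`, `run_index`, `run_type`, `r_t1t2`, `r_t1c`,
#'   `r_t2c`, `z_t1t2`, `z_t1c`, `z_t2c`, `composite`.
#' @export
pairwiseConnectivity <- function(run) {
  stopifnot(is(run, "RoiRun"))
  s <- run@series
  if (nrow(s) < 3L) stop("need at least 3 samples to estimate correlations")
  sds <- apply(s, 2, stats::sd)
  if (any(sds == 0))
    stop("constant series for ROI: ",
         paste(colnames(s)[sds == 0], collapse = ", "))
  r <- stats::cor(s)
  r12 <- r[1, 2]; r1c <- r[1, 3]; r2c <- r[2, 3]
  data.frame(
    subject = run@subject, day = run@day, run_index = run@runIndex,
    run_type = run@runType,
    r_t1t2 = r12, r_t1c = r1c, r_t2c = r2c,
    z_t1t2 = fisherZ(r12), z_t1c = fisherZ(r1c), z_t2c = fisherZ(r2c),
    composite = compositeMeasure(r12, r1c, r2c),
    stringsAsFactors = FALSE)
}

#' Connectivity records for a collection of runs
#'
#' @param runs list of [RoiRun-class] objects (e.g. from
#'   [generateRoiCohort()]).
#' @return a `ConnectivityRecord` data.frame, one row per run.
#' @export
connectivityRecords <- function(runs) {
  do.call(rbind, lapply(runs, pairwiseConnectivity))
}

#' Validate the two-point proxy against offline Pearson correlation
#'
#' For each run, computes the two-point agreement score (fired fraction)
#' and the offline Pearson correlation between the two targets, then
#' correlates the two across runs, with a permutation p-value obtained by
#' shuffling the run pairing. When subjects are available the report also
#' includes the pooled-across-runs correlation computed within each
#' subject (mean and range), since pooling convention affects the
#' estimate.
#'
#' @param runs list of at least 10 [RoiRun-class] objects.
#' @param k window length for the proxy score (default 2, the deployed
#'   rule).
#' @param nPermutations label shufflings for the p-value.
#' @param seed RNG seed for the permutations.
#' @return a list with elements `perRun` (data.frame: subject, proxy,
#'   pearson), `correlation`, `pValue`, `nPermutations`,
#'   `withinSubject` (data.frame of per-subject correlations, or NULL),
#'   and `degenerate` (TRUE when the proxy scores have zero variance, in
#'   which case `correlation` is NA).
#' @export
validateProxy <- function(runs, k = 2L, nPermutations = 5000L, seed = 1L) {
  if (length(runs) < 10L) stop("need at least 10 runs to validate the proxy")
  proxy <- vapply(runs, kpointAgreementScore, numeric(1), k = k)
  pearson <- vapply(runs, function(r) stats::cor(r@series[, 1], r@series[, 2]),
                    numeric(1))
  subj <- vapply(runs, function(r) r@subject, character(1))
  perRun <- data.frame(subject = subj, proxy = proxy, pearson = pearson,
                       stringsAsFactors = FALSE)
  if (stats::sd(proxy) == 0 || stats::sd(pearson) == 0) {
    return(list(perRun = perRun, correlation = NA_real_, pValue = NA_real_,
                nPermutations = as.integer(nPermutations),
                withinSubject = NULL, degenerate = TRUE))
  }
  obs <- stats::cor(proxy, pearson)
  nullStats <- withSeed(seed, vapply(seq_len(nPermutations), function(i)
    stats::cor(proxy, sample(pearson)), numeric(1)))
  withinSubject <- NULL
  if (length(unique(subj)) > 1L) {
    per <- vapply(split(perRun, perRun$subject), function(d) {
      if (nrow(d) < 3L || stats::sd(d$proxy) == 0 || stats::sd(d$pearson) == 0)
        NA_real_
      else stats::cor(d$proxy, d$pearson)
    }, numeric(1))
    withinSubject <- data.frame(subject = names(per), correlation = unname(per),
                                stringsAsFactors = FALSE)
  }
  list(perRun = perRun, correlation = obs,
       pValue = permPValue(nullStats, obs),
       nPermutations = as.integer(nPermutations),
       withinSubject = withinSubject, degenerate = FALSE)
}
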