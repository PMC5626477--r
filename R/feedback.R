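#' Two-point covert feedback decision for one TR transition
#'
#' Implements the real-time rule: the signal trend (mean signal at TR t
#' minus TR t-1) is computed for each of the three ROIs, and feedback
#' fires iff the two targets trend in the same direction while the
#' control trends in the opposite direction. The published rule is stated
#' as sign conditions on ratios of increments; this implementation
#' compares increment signs directly, which is algebraically equivalent
#' for nonzero increments and avoids 0/0. An exactly zero increment in
#' any ROI never fires (conservative tie rule; zero increments have
#' measure zero for continuous signals).
#'
#' @param prev,curr length-3 numeric vectors of ROI mean signals
#'   (target1, target2, control) at TR t-1 and t.
#' @param tr optional TR index used in error messages.
#' @return a list with elements `tr`, `dTarget1`, `dTarget2`, `dControl`
#'   (signed increments) and `fired` (logical).
#' @examples
#' decideFeedback(c(0, 0, 0), c(1, 0.5, -1))$fired   # TRUE
#' decideFeedback(c(0, 0, 0), c(1, -0.5, -1))$fired  # FALSE
#' @export
decideFeedback <- function(prev, curr, tr = NA_integer_) {
  if (length(prev) != 3L || length(curr) != 3L)
    stop("prev and curr must each hold the three ROI signals")
  if (anyNA(prev) || anyNA(curr))
    stop("missing ROI sample at TR ", tr)
  d <- curr - prev
  s <- sign(d)
  fired <- s[1] != 0 && s[1] == s[2] && s[3] == -s[1]
  list(tr = tr, dTarget1 = d[1], dTarget2 = d[2], dControl = d[3],
       fired = fired)
}

#' Run the streaming feedback engine over a run
#'
#' Processes a run TR by TR, strictly causally: the decision at TR t uses
#' only samples up to t. Produces one decision per TR transition
#' (`nTR - 1` decisions) and the puzzle bookkeeping: every fired decision
#' reveals one piece; each completed 25-piece board increments the board
#' count.
#'
#' @param run a [RoiRun-class].
#' @param boardSize puzzle pieces per board (25 in the study).
#' @return a [FeedbackLog-class].
#' @examples
#' run <- RoiRun(cbind(1:10, 1:10, 10:1))
#' piecesRevealed(runFeedbackSession(run))
#' @export
runFeedbackSession <- function(run, boardSize = 25L) {
  stopifnot(is(run, "RoiRun"))
  s <- run@series
  n <- nrow(s)
  tr <- integer(n - 1L)
  d1 <- d2 <- dc <- numeric(n - 1L)
  fired <- logical(n - 1L)
  for (t in 2:n) {
    dec <- decideFeedback(s[t - 1L, ], s[t, ], tr = t)
    i <- t - 1L
    tr[i] <- t
    d1[i] <- dec$dTarget1
    d2[i] <- dec$dTarget2
    dc[i] <- dec$dControl
    fired[i] <- dec$fired
  }
  pieces <- sum(fired)
  new("FeedbackLog",
      subject = run@subject, day = run@day, runIndex = run@runIndex,
      decisions = data.frame(tr = tr, dTarget1 = d1, dTarget2 = d2,
                             dControl = dc, fired = fired),
      piecesRevealed = as.integer(pieces),
      boardsCompleted = as.integer(pieces %/% boardSize),
      boardSize = as.integer(boardSize))
}

#' Fired fraction of a feedback log
#'
#' @param log a [FeedbackLog-class].
#' @return fraction of decisions that fired.
#' @export
firedFraction <- function(log) {
  stopifnot(is(log, "FeedbackLog"))
  mean(log@decisions$fired)
}

#' k-point sliding-window agreement score
#'
#' Generalisation of the two-point rule to longer windows, as explored in
#' simulation during the study's design: for `k = 2` the score is exactly
#' the fired fraction of the two-point rule; for `k` in 3..6 the score is
#' the fraction of length-`k` sliding windows (stride 1) whose
#' within-window Pearson correlation is positive between the two targets
#' and negative between target1 and control. Windows where either
#' correlation is undefined (a constant series) do not count as
#' agreement.
#'
#' @param run a [RoiRun-class].
#' @param k window length, 2 to 6.
#' @return the per-run score, a fraction between 0 and 1.
#' @export
kpointAgreementScore <- function(run, k = 2L) {
  stopifnot(is(run, "RoiRun"))
  k <- as.integer(k)
  if (k < 2L || k > 6L) stop("k must lie in 2..6")
  s <- run@series
  n <- nrow(s)
  if (n < k) stop("run has fewer samples than the window length")
  if (k == 2L) return(firedFraction(runFeedbackSession(run)))
  nWin <- n - k + 1L
  hits <- logical(nWin)
  for (w in seq_len(nWin)) {
    idx <- w:(w + k - 1L)
    t1 <- s[idx, 1]; t2 <- s[idx, 2]; cc <- s[idx, 3]
    if (stats::sd(t1) == 0 || stats::sd(t2) == 0 || stats::sd(cc) == 0) next
    hits[w] <- stats::cor(t1, t2) > 0 && stats::cor(t1, cc) < 0
  }
  mean(hits)
}
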