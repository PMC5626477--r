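# Internal helpers shared across modules.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Derive a stream-specific child seed from a base seed (kept < 2^31).
childSeed <- function(seed, ...) {
  offs <- sum(utf8ToInt(paste(..., sep = "/")) * seq_along(utf8ToInt(paste(..., sep = "/"))))
  as.integer((as.numeric(seed) * 48271 + offs) %% 2147483629)
}

#' Build a 3x3 inter-ROI correlation matrix from its three pairwise values
#'
#' @param t1t2,t1c,t2c pairwise correlations target1-target2,
#'   target1-control and target2-control.
#' @param names row/column names (default the three ROI names).
#' @return a symmetric 3x3 matrix with unit diagonal.
#' @examples
#' corrMatrix3(0.5, 0.2, 0.1)
#' @export
corrMatrix3 <- function(t1t2, t1c, t2c, names = c("target1", "target2", "control")) {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- t1t2
  m[1, 3] <- m[3, 1] <- t1c
  m[2, 3] <- m[3, 2] <- t2c
  dimnames(m) <- list(names, names)
  m
}

# Extract (t1t2, t1c, t2c) from a 3x3 correlation matrix.
pairValues <- function(m) c(t1t2 = m[1, 2], t1c = m[1, 3], t2c = m[2, 3])

#' Nearest positive-semidefinite repair of a correlation matrix
#'
#' Clips negative eigenvalues to a small nonnegative floor, reconstructs
#' the matrix, and rescales it back to unit diagonal. Used by the cohort
#' generators when `repairPsd = TRUE`.
#'
#' @param m symmetric matrix with unit diagonal.
#' @param eps eigenvalue floor.
#' @return the repaired correlation matrix.
#' @export
nearestPSD <- function(m, eps = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  r <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(r))
  r <- r / tcrossprod(d)
  diag(r) <- 1
  dimnames(r) <- dimnames(m)
  (r + t(r)) / 2
}

isPSD <- function(m, tol = 1e-10) {
  min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) >= -tol
}

# Permutation p-value with add-one smoothing (never exactly 0).
permPValue <- function(nullStats, observed, twoTailed = TRUE) {
  if (twoTailed) {
    (1 + sum(abs(nullStats) >= abs(observed))) / (length(nullStats) + 1)
  } else {
    (1 + sum(nullStats >= observed)) / (length(nullStats) + 1)
  }
}
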