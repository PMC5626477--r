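# A reference change sample with mean exactly 0 and SD exactly 5.
exactReference <- function(n = 20, sd = 5) {
  x <- rnorm(n)
  as.numeric(scale(x)) * sd
}

test_that("the 3-SD rule flags exactly the constructed cases", {
  set.seed(81)
  ref <- exactReference()
  tab <- data.frame(subject = c("a", "b", "c"),
                    srs_change = c(16, 14.9, -16))
  out <- flagOutliers(tab, ref)
  expect_identical(out$outlier_flag, c(TRUE, FALSE, TRUE))
  expect_match(out$outlier_reason[1], "16")
  within <- data.frame(subject = letters[1:5], srs_change = rnorm(5, 0, 2))
  expect_false(any(flagOutliers(within, ref)$outlier_flag))
})

test_that("widening the SD multiplier never flags more subjects", {
  set.seed(82)
  ref <- exactReference()
  tab <- data.frame(subject = sprintf("s%02d", 1:30),
                    srs_change = rnorm(30, 0, 10))
  flagsAt <- function(m) sum(flagOutliers(tab, ref, multiplier = m)$outlier_flag)
  counts <- vapply(c(1, 1.5, 2, 2.5, 3, 4), flagsAt, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("degenerate or undersized reference samples are refused", {
  tab <- data.frame(subject = "a", srs_change = 1)
  expect_error(flagOutliers(tab, rep(0, 20)), "zero standard deviation")
  expect_error(flagOutliers(tab, rnorm(5)), "at least 10")
})

test_that("noiseless linear linkage yields r = 1 and outliers attenuate it", {
  conn <- seq(0.01, 0.3, length.out = 12)
  behav <- 30 * conn
  res <- brainBehaviorCorrelation(conn, behav, nPermutations = 200, seed = 1)
  expect_equal(res$excluding$r, 1)
  expect_lt(res$excluding$p, 0.05)

  # two large-negative-change outliers in a positively linked cohort
  connO <- c(conn, 0.25, 0.28)
  behavO <- c(behav, -40, -45)
  flags <- c(rep(FALSE, 12), TRUE, TRUE)
  resO <- brainBehaviorCorrelation(connO, behavO, outlierFlags = flags,
                                   nPermutations = 200, seed = 2)
  expect_lt(resO$including$r, resO$excluding$r)
  expect_identical(resO$nOutliers, 2L)
})

test_that("zero-variance inputs are reported as undefined", {
  res <- brainBehaviorCorrelation(rep(0.2, 8), rnorm(8), nPermutations = 200)
  expect_true(res$excluding$degenerate)
  expect_true(is.na(res$excluding$r))
})

test_that("brain-behaviour permutation test is calibrated under the null", {
  set.seed(83)
  rejected <- mean(replicate(400, {
    conn <- rnorm(15); behav <- rnorm(15)
    brainBehaviorCorrelation(conn, behav, nPermutations = 199,
                             seed = sample.int(1e6, 1))$excluding$p < 0.05
  }))
  expect_gte(rejected, 0.02)
  expect_lte(rejected, 0.08)
})

test_that("partial correlation matches the closed-form identity", {
  set.seed(84)
  n <- 60
  z <- rnorm(n)
  x <- 0.7 * z + rnorm(n)
  y <- 0.5 * z + rnorm(n)
  res <- partialBrainBehavior(x, y, z, nPermutations = 200, seed = 1)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  closedForm <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_lt(abs(res$r - closedForm), 1e-10)
})

test_that("an irrelevant covariate leaves the correlation almost unchanged", {
  set.seed(85)
  n <- 4000
  x <- rnorm(n); y <- 0.5 * x + rnorm(n); z <- rnorm(n)
  res <- partialBrainBehavior(x, y, z, nPermutations = 100, seed = 1)
  expect_lt(abs(res$r - cor(x, y)), 0.02)
})

test_that("a shared confounder is removed by partialling", {
  set.seed(86)
  n <- 2000
  z <- rnorm(n)
  x <- z + rnorm(n); y <- z + rnorm(n)
  simple <- cor(x, y)
  res <- partialBrainBehavior(x, y, z, nPermutations = 100, seed = 1)
  expect_gt(simple, 0.3)
  expect_lt(abs(res$r), 0.06)
})

test_that("degenerate and rank-deficient covariates are handled explicitly", {
  set.seed(87)
  x <- rnorm(20); y <- rnorm(20)
  res <- partialBrainBehavior(x, y, y, nPermutations = 100)
  expect_true(res$degenerate)
  z <- rnorm(20)
  expect_error(partialBrainBehavior(x, y, cbind(z, 2 * z),
                                    nPermutations = 100), "collinear")
})
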