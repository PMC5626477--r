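makeRecords <- function(composites, runTypes, runIndex = seq_along(composites),
                        subject = "sub01", day = "day1") {
  data.frame(subject = subject, day = day, run_index = runIndex,
             run_type = runTypes,
             r_t1t2 = composites, r_t1c = 0, r_t2c = 0,
             z_t1t2 = composites, z_t1c = 0, z_t2c = 0,
             composite = composites, stringsAsFactors = FALSE)
}

test_that("day aggregation averages exactly the runs in scope", {
  rec <- makeRecords(c(0.7, 0.8, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
                     c("rest", "rest", "feedback", "feedback", "feedback",
                       "feedback", "rest", "rest"))
  expect_equal(aggregateByDay(rec, "feedback_all")$composite, 0.25)
  expect_equal(aggregateByDay(rec, "feedback_first2")$composite, 0.15)
  expect_equal(aggregateByDay(rec, "rest_pre")$composite, 0.75)
  expect_equal(aggregateByDay(rec, "rest_post")$composite, 0.55)
  # rest_pre is isolated from feedback runs entirely
  rec2 <- rec
  rec2$composite[rec2$run_type == "feedback"] <- 99
  expect_identical(aggregateByDay(rec, "rest_pre"),
                   aggregateByDay(rec2, "rest_pre"))
})

test_that("aggregation fails listing subject-days without runs in scope", {
  rec <- rbind(makeRecords(0.1, "feedback", subject = "sub01"),
               makeRecords(0.2, "rest", subject = "sub02"))
  expect_error(aggregateByDay(rec, "feedback_all"), "sub02")
})

test_that("uniform positive change attains the smallest permutation p", {
  ch <- setNames(rep(0.2, 17), sprintf("sub%02d", 1:17))
  summ <- summariesFromValues(list(day1 = ch * 0, day4 = ch))
  res <- dayContrastPermutation(summ, "day1", "day4", nIterations = 5000,
                                seed = 1)
  expect_equal(res$meanChange, 0.2)
  expect_equal(res$p, 1 / 5001)
})

test_that("zero observed change gives a large permutation p", {
  ch <- setNames(c(-0.2, 0.2, -0.1, 0.1, -0.3, 0.3), sprintf("s%d", 1:6))
  summ <- summariesFromValues(list(day1 = ch * 0, day4 = ch))
  res <- dayContrastPermutation(summ, "day1", "day4", nIterations = 1000,
                                seed = 2)
  expect_gt(res$p, 0.5)
})

test_that("Monte-Carlo permutation p agrees with exhaustive sign-flip enumeration", {
  set.seed(7)
  for (rep in 1:3) {
    ch <- setNames(rnorm(10, mean = 0.4, sd = 1), sprintf("s%02d", 1:10))
    summ <- summariesFromValues(list(day1 = ch * 0, day4 = ch))
    exact <- exhaustiveSignFlipP(ch)
    mc <- dayContrastPermutation(summ, "day1", "day4", nIterations = 4000,
                                 seed = 100 + rep)$p
    expect_lt(abs(mc - exact), 3 * sqrt(exact * (1 - exact) / 4000) + 1e-3)
  }
})

test_that("permutation p is invariant to rescaling of the measure", {
  ch <- setNames(rnorm(12, 0.1), sprintf("s%02d", 1:12))
  p1 <- dayContrastPermutation(summariesFromValues(list(a = ch * 0, b = ch)),
                               "a", "b", nIterations = 500, seed = 3)$p
  p2 <- dayContrastPermutation(summariesFromValues(list(a = ch * 0, b = ch * 7.3)),
                               "a", "b", nIterations = 500, seed = 3)$p
  expect_identical(p1, p2)
})

test_that("contrasts refuse unpaired subjects and tiny iteration counts", {
  summ <- summariesFromValues(list(day1 = c(sub01 = 0, sub02 = 0),
                                   day4 = c(sub01 = 0.1)))
  expect_error(dayContrastPermutation(summ, "day1", "day4"), "sub02")
  summ2 <- summariesFromValues(list(day1 = c(sub01 = 0, sub02 = 0),
                                    day4 = c(sub01 = 1, sub02 = 1)))
  expect_error(dayContrastPermutation(summ2, "day1", "day4", nIterations = 50),
               "at least 100")
})

test_that("subset enumeration counts and constancy behave as expected", {
  ch <- setNames(rep(0.2, 17), sprintf("sub%02d", 1:17))
  summ <- summariesFromValues(list(day1 = ch * 0, day4 = ch))
  res <- subsetRobustness(summ, subsetSize = 10, dayA = "day1", dayB = "day4",
                          nIterations = 200, seed = 1)
  expect_equal(res$nSubsets, choose(17, 10))
  expect_true(all(abs(res$meanChanges - 0.2) < 1e-12))
  expect_identical(res$fractionSignificant, 1)
  # boundary: subset size equal to the cohort reproduces the full result
  ch10 <- setNames(rnorm(10, 0.2, 0.05), sprintf("s%02d", 1:10))
  summ10 <- summariesFromValues(list(day1 = ch10 * 0, day4 = ch10))
  one <- subsetRobustness(summ10, subsetSize = 10, dayA = "day1",
                          dayB = "day4", nIterations = 200, seed = 2)
  expect_identical(one$nSubsets, 1L)
  expect_equal(one$meanChanges, mean(ch10))
})

test_that("combinatorial explosions are refused without a sampling flag", {
  ch <- setNames(rnorm(40), sprintf("s%02d", 1:40))
  summ <- summariesFromValues(list(day1 = ch * 0, day4 = ch))
  expect_error(subsetRobustness(summ, subsetSize = 20, dayA = "day1",
                                dayB = "day4"), "sampleSubsets")
  sampled <- subsetRobustness(summ, subsetSize = 20, dayA = "day1",
                              dayB = "day4", nIterations = 200,
                              sampleSubsets = 50, seed = 1)
  expect_identical(sampled$nSubsets, 50L)
})

test_that("Welch interaction test matches the hand-computed example", {
  res <- groupInteraction(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674, tolerance = 0.001 / 3.674)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.0213, tolerance = 0.001 / 0.0213)
  same <- groupInteraction(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  degenerate <- groupInteraction(c(2, 2), c(2, 2))
  expect_identical(degenerate$p, 1)
})

test_that("Welch test is calibrated under unequal-variance nulls", {
  set.seed(8)
  rejections <- mean(replicate(1000, {
    groupInteraction(rnorm(17, 0, 1), rnorm(10, 0, 3))$p < 0.05
  }))
  expect_lt(abs(rejections - 0.05), 0.02)
})

test_that("retention analysis recovers exact linear decay and degenerates cleanly", {
  subj <- sprintf("s%02d", 1:12)
  weeks <- setNames(seq(5, 56, length.out = 12), subj)
  day1 <- setNames(rep(0, 12), subj)
  day4 <- setNames(rep(0.2, 12), subj)
  fu <- day4 * (1 - 0.01 * weeks)
  summ <- summariesFromValues(list(day1 = day1, day4 = day4, followup = fu))
  res <- retentionAnalysis(summ, weeks, nPermutations = 500, seed = 1)
  expect_equal(res$r, -1)
  expect_equal(unname(res$retention), unname(1 - 0.01 * weeks))

  # all follow-up values equal to day4: retention constant, r undefined
  summConst <- summariesFromValues(list(day1 = day1, day4 = day4,
                                        followup = day4))
  resConst <- retentionAnalysis(summConst, weeks, nPermutations = 500)
  expect_true(resConst$degenerate)
  expect_true(is.na(resConst$r))

  # zero trained change excludes the subject with a warning
  day4z <- day4; day4z["s01"] <- 0
  summZ <- summariesFromValues(list(day1 = day1, day4 = day4z, followup = fu))
  expect_warning(resZ <- retentionAnalysis(summZ, weeks, nPermutations = 500),
                 "excluded")
  expect_identical(resZ$nExcluded, 1L)
})

test_that("retention p-value is well calibrated under a null linkage", {
  set.seed(9)
  ps <- replicate(200, {
    subj <- sprintf("s%02d", 1:12)
    weeks <- setNames(runif(12, 5, 56), subj)
    day1 <- setNames(rep(0, 12), subj)
    day4 <- setNames(rep(0.2, 12), subj)
    fu <- setNames(0.2 * runif(12, 0.5, 1), subj)
    summ <- summariesFromValues(list(day1 = day1, day4 = day4, followup = fu))
    retentionAnalysis(summ, weeks, nPermutations = 99,
                      seed = sample.int(1e6, 1))$p
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
  expect_lt(abs(median(ps) - 0.5), 0.15)
})
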