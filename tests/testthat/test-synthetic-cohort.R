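test_that("uncorrelated spec yields near-zero empirical correlations", {
  spec <- quickSpec(nTR = 10000L, seed = 11)
  runs <- generateRoiCohort(spec)
  r <- cor(roiSeries(runs[[1]]))
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
})

test_that("programmed correlations are hit at large n", {
  spec <- quickSpec(nTR = 10000L, t1t2 = 0.9, seed = 12)
  runs <- generateRoiCohort(spec)
  r <- cor(roiSeries(runs[[1]]))
  expect_equal(r[1, 2], 0.9, tolerance = 0.02 / 0.9)
  # AR filtering with shared coefficient preserves innovation correlations
  specAr <- quickSpec(nTR = 10000L, t1t2 = 0.6, arCoeff = 0.5, seed = 13)
  rAr <- cor(roiSeries(generateRoiCohort(specAr)[[1]]))
  expect_equal(rAr[1, 2], 0.6, tolerance = 0.05)
})

test_that("same spec and seed regenerate bit-identical series", {
  spec <- quickSpec(nSubjects = 2L, nTR = 50L, t1t2 = 0.4, arCoeff = 0.3,
                    driftAmplitude = 0.3, seed = 99, feedback = 2L,
                    restPre = 1L)
  a <- generateRoiCohort(spec)
  b <- generateRoiCohort(spec)
  expect_identical(lapply(a, roiSeries), lapply(b, roiSeries))
  # and a different seed changes the data
  c <- generateRoiCohort(quickSpec(nSubjects = 2L, nTR = 50L, t1t2 = 0.4,
                                   arCoeff = 0.3, driftAmplitude = 0.3,
                                   seed = 100, feedback = 2L, restPre = 1L))
  expect_false(identical(roiSeries(a[[1]]), roiSeries(c[[1]])))
})

test_that("cohort structure follows the run plan", {
  spec <- CohortSpec(nSubjects = 2L, days = c("day1", "day2"), nTR = 20L,
                     seed = 1)
  runs <- generateRoiCohort(spec)
  expect_length(runs, 2 * 2 * 8)
  types <- vapply(runs, runType, character(1))
  expect_identical(unname(types[1:8]),
                   c("rest", "rest", "feedback", "feedback", "feedback",
                     "feedback", "rest", "rest"))
  expect_identical(nrow(roiSeries(runs[[1]])), 20L)
})

test_that("AR(1) autocorrelation and drift are present as programmed", {
  spec <- quickSpec(nTR = 8000L, arCoeff = 0.5, seed = 21)
  x <- roiSeries(generateRoiCohort(spec)[[1]])[, 1]
  expect_equal(cor(x[-1], x[-length(x)]), 0.5, tolerance = 0.1)
  # drift inflates variance by about amplitude^2 / 2
  specD <- quickSpec(nTR = 8000L, driftAmplitude = 1, seed = 22)
  v <- var(roiSeries(generateRoiCohort(specD)[[1]])[, 1])
  expect_equal(v, 1.5, tolerance = 0.15)
})

test_that("non-PSD requests are rejected naming the day, or repaired on demand", {
  mkSpec <- function(repair) quickSpec(nTR = 30L, t1t2 = 0.9, t1c = 0.9,
                                       t2c = -0.9, seed = 5,
                                       repairPsd = repair)
  expect_error(generateRoiCohort(mkSpec(FALSE)), "day1.*not positive")
  runs <- generateRoiCohort(mkSpec(TRUE))
  expect_identical(attr(runs, "repairedDays"), "day1")
  # and the repaired matrix is a valid correlation matrix
  m <- nearestPSD(corrMatrix3(0.9, 0.9, -0.9))
  expect_equal(diag(m), c(target1 = 1, target2 = 1, control = 1))
  expect_gte(min(eigen(m, symmetric = TRUE)$values), -1e-10)
})

test_that("behavior generator links SRS change to connectivity change", {
  change <- setNames(seq(-0.1, 0.3, length.out = 12), sprintf("sub%02d", 1:12))
  exact <- generateBehavior(change, slope = 1, noiseSd = 1e-12, seed = 2)
  expect_equal(cor(exact$srs_change, change), 1, tolerance = 1e-6)
  expect_equal(exact$srs_pre - exact$srs_post, exact$srs_change)

  bigChange <- setNames(rnorm(1000), sprintf("s%04d", 1:1000))
  nullLink <- generateBehavior(bigChange, slope = 0, noiseSd = 1, seed = 3)
  expect_lt(abs(cor(nullLink$srs_change, bigChange)), 0.08)
})

test_that("injected outliers are exactly those flagged by the 3-SD rule", {
  change <- setNames(rnorm(15, 0, 0.05), sprintf("sub%02d", 1:15))
  ref <- generateReferenceChanges(n = 40, sd = 5, seed = 9)
  tab <- generateBehavior(change, slope = 10, noiseSd = 1, nOutliers = 2L,
                          referenceChanges = ref, seed = 4)
  flagged <- flagOutliers(tab, ref)
  expect_identical(sum(flagged$outlier_flag), 2L)
  expect_identical(flagged$outlier_flag, flagged$injected_outlier)
})

test_that("sphere masks match a direct lattice enumeration", {
  g <- c(24L, 24L, 24L)
  vox <- 3.2
  centre <- c(0, 0, 0)
  mask <- sphereMask(g, vox, centre, 4)
  co <- expand.grid(i = 1:24, j = 1:24, k = 1:24)
  mm <- (as.matrix(co) - (24 + 1) / 2) * vox
  inside <- rowSums(sweep(mm, 2, centre)^2) <= 16
  expect_identical(as.vector(mask), inside)
  expect_gte(sum(mask), 1)
  expect_lte(sum(mask), 19)
})

test_that("spheres that do not fit are rejected with the required shape", {
  expect_error(sphereMask(c(4L, 4L, 4L), 3.2, c(0, 0, 0), 8),
               "minimum gridShape")
})

test_that("voxel grid geometry is valid and Talairach centres fit large grids", {
  vs <- VoxelGridSpec()
  masks <- roiMasks(vs)
  expect_true(all(vapply(masks, sum, 1) >= 1))
  expect_lte(max(Reduce(`+`, masks)), 1)
  expect_lte(max(Reduce(`+`, networkMasks(vs))), 1)
  # ROI spheres nest inside their network spheres
  expect_true(all(mapply(function(roi, net) all(net[roi]),
                         masks, networkMasks(vs))))
  assign <- networkAssignment(vs)
  expect_setequal(unique(as.vector(assign)),
                  c("background", "network1", "network2", "control_network"))
  vsTal <- VoxelGridSpec(gridShape = c(48L, 48L, 48L),
                         roiCenters = talairachCenters())
  expect_true(all(vapply(roiMasks(vsTal), sum, 1) >= 1))
  expect_error(VoxelGridSpec(roiCenters = talairachCenters()),
               "minimum gridShape")
})

test_that("background voxels are uncoupled and voxel runs are deterministic", {
  days <- c("day1", "day4")
  cs <- CohortSpec(nSubjects = 1L, days = days,
                   runsPerDay = c(rest_pre = 0L, feedback = 1L, rest_post = 0L),
                   nTR = 10000L, arCoeff = 0, driftAmplitude = 0, seed = 31)
  traj <- lapply(days, function(d) corrMatrix3(0, 0, 0,
    names = c("network1", "network2", "control_network")))
  names(traj) <- days
  vs <- VoxelGridSpec(gridShape = c(12L, 12L, 12L),
                      couplingTrajectory = traj)
  runs <- generateVoxelCohort(vs, cs, days = "day1")
  nets <- attr(runs, "networkMasks")
  X <- runs[[1]]@data
  n1mean <- colMeans(X[as.vector(nets$target1), ])
  background <- which(!as.vector(Reduce(`|`, nets)))[1]
  expect_lt(abs(cor(X[background, ], n1mean)), 0.05)
  # zero programmed coupling: the two network means stay uncorrelated
  n2mean <- colMeans(X[as.vector(nets$target2), ])
  expect_lt(abs(cor(n1mean, n2mean)), 0.05)
  runs2 <- generateVoxelCohort(vs, cs, days = "day1")
  expect_identical(runs[[1]]@data, runs2[[1]]@data)
})

test_that("programmed coupling increases are recovered from network means", {
  days <- c("day1", "day4")
  nRunsPerDay <- 10L
  cs <- CohortSpec(nSubjects = 1L, days = days,
                   runsPerDay = c(rest_pre = 0L, feedback = nRunsPerDay,
                                  rest_post = 0L),
                   nTR = 600L, arCoeff = 0, driftAmplitude = 0, seed = 33)
  traj <- list(
    day1 = corrMatrix3(0.1, 0, 0, names = c("network1", "network2",
                                            "control_network")),
    day4 = corrMatrix3(0.4, 0, 0, names = c("network1", "network2",
                                            "control_network")))
  vs <- VoxelGridSpec(gridShape = c(12L, 12L, 12L), couplingTrajectory = traj)
  nets <- networkMasks(vs)
  meanR <- function(day) {
    runs <- generateVoxelCohort(vs, cs, days = day)
    mean(vapply(runs, function(r) {
      cor(colMeans(r@data[as.vector(nets$target1), ]),
          colMeans(r@data[as.vector(nets$target2), ]))
    }, numeric(1)))
  }
  # network means attenuate the latent correlation by a known factor
  a2 <- vs@voxelLoading^2
  k <- sum(nets$target1)
  atten <- a2 / (a2 + (1 - a2) / k)
  expect_equal(meanR("day4") - meanR("day1"), 0.3 * atten, tolerance = 0.05 / 0.3)
})
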