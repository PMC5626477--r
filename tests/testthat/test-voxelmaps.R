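# Small deterministic voxel fixtures: grid 5x5x5, seed mask at one corner,
# reference mask at the opposite corner.
tinyMasks <- function() {
  seed <- array(FALSE, c(5, 5, 5)); seed[1:2, 1, 1] <- TRUE
  ref <- array(FALSE, c(5, 5, 5)); ref[4:5, 5, 5] <- TRUE
  list(seed = seed, ref = ref)
}

tinyRun <- function(noiseSeed, nTR = 40) {
  set.seed(noiseSeed)
  data <- matrix(rnorm(125 * nTR), 125, nTR)
  voxelRunFromMatrix(data, c(5, 5, 5))
}

test_that("cluster labelling matches a flood-fill oracle on random masks", {
  set.seed(61)
  for (i in 1:25) {
    mask <- array(runif(125) < 0.35, c(5, 5, 5))
    expect_identical(covertnf:::.maxClusterSize6(as.vector(mask), dim(mask)),
                     oracleMaxCluster(mask))
    labels <- covertnf:::.labelClusters6(as.vector(mask), dim(mask))
    expect_identical(as.vector(labels > 0), as.vector(mask))
  }
})

test_that("a voxel identical to the seed series shows zero change", {
  m <- tinyMasks()
  mkRun <- function(s) {
    run <- tinyRun(noiseSeed = s)
    # make every seed voxel carry the same series
    run@data[as.vector(m$seed), ] <-
      matrix(run@data[which(m$seed)[1], ], sum(m$seed), ncol(run@data),
             byrow = TRUE)
    run
  }
  ch <- seedChangeMap(list(mkRun(1)), list(mkRun(2)), m$seed)
  expect_equal(ch[which(m$seed)], rep(0, 2))
  expect_identical(attr(ch, "flaggedMask"), m$seed)
})

test_that("using the seed as its own reference gives an identically zero map", {
  m <- tinyMasks()
  ch <- seedChangeMap(list(tinyRun(1)), list(tinyRun(2)), m$seed,
                      referenceMask = m$seed)
  expect_true(all(abs(ch) < 1e-14))
})

test_that("swapping seed and reference negates the differential map", {
  m <- tinyMasks()
  a <- seedChangeMap(list(tinyRun(3)), list(tinyRun(4)), m$seed, m$ref)
  b <- seedChangeMap(list(tinyRun(3)), list(tinyRun(4)), m$ref, m$seed)
  expect_equal(as.vector(a), -as.vector(b))
})

test_that("swapping the two days negates the change map (sign-flip null validity)", {
  m <- tinyMasks()
  runsA <- list(tinyRun(5), tinyRun(6))
  runsB <- list(tinyRun(7), tinyRun(8))
  fwd <- seedChangeMap(runsA, runsB, m$seed, m$ref)
  rev <- seedChangeMap(runsB, runsA, m$seed, m$ref)
  expect_equal(as.vector(fwd), -as.vector(rev))
})

test_that("constant voxels are marked undefined and counted", {
  m <- tinyMasks()
  runA <- tinyRun(9); runB <- tinyRun(10)
  runA@data[100, ] <- 5
  runB@data[100, ] <- 5
  ch <- seedChangeMap(list(runA), list(runB), m$seed)
  expect_true(is.na(ch[100]))
  expect_identical(attr(ch, "nUndefined"), 1L)
  tt <- groupTtestMap(list(ch, ch, ch))
  expect_identical(tt$nExcluded, 1L)
  expect_true(is.na(tt$t[100]))
})

test_that("group t map handles exact zeros and near-zero variance", {
  zeros <- array(0, c(4, 4, 4))
  tt <- groupTtestMap(list(zeros, zeros, zeros))
  expect_equal(tt$t[1], 0)
  expect_equal(tt$p[1], 1)
  set.seed(62)
  jitter <- lapply(1:17, function(i) array(0.2 + rnorm(64, sd = 1e-6),
                                           c(4, 4, 4)))
  tj <- groupTtestMap(jitter)
  expect_lt(max(tj$p), 1e-10)
})

test_that("voxelwise p-values are calibrated on null grids", {
  set.seed(63)
  maps <- lapply(1:8, function(i) array(rnorm(12^3), c(12, 12, 12)))
  tt <- groupTtestMap(maps)
  expect_lt(abs(mean(tt$p < 0.05) - 0.05), 0.02)
})

test_that("cluster correction with a single threshold has union = that mask", {
  set.seed(64)
  maps <- lapply(1:6, function(i) array(rnorm(10^3), c(10, 10, 10)))
  res <- clusterPermutationCorrect(maps, thresholds = 0.05,
                                   nPermutations = 200, seed = 5)
  expect_identical(unionMask(res), res@survivorMasks[["0.05"]])
  expect_identical(res@connectivity, "6")
  expect_error(clusterPermutationCorrect(maps, thresholds = 0.05,
                                         nPermutations = 50), "at least 100")
})

test_that("a planted localized effect survives correction and peaks inside it", {
  set.seed(65)
  shape <- c(12, 12, 12)
  effect <- array(FALSE, shape); effect[5:7, 5:7, 5:7] <- TRUE
  maps <- lapply(1:10, function(i) {
    m <- array(rnorm(prod(shape), 0, 0.1), shape)
    m[effect] <- m[effect] + 0.3
    m
  })
  res <- clusterPermutationCorrect(maps, nPermutations = 300, seed = 6)
  expect_gt(sum(unionMask(res) & effect), 0.9 * sum(effect))
  tt <- groupTtestMap(maps)
  peaks <- clusterPeaks(tt$t, unionMask(res))
  top <- peaks[which.max(abs(peaks$peakT)), ]
  expect_true(effect[top$peakI, top$peakJ, top$peakK])
})

test_that("peak reporting never returns voxels inside the excluded masks", {
  tmap <- array(0, c(6, 6, 6))
  mask <- array(FALSE, c(6, 6, 6))
  mask[1:3, 1, 1] <- TRUE
  tmap[1:3, 1, 1] <- c(10, 5, 4)   # largest |t| sits in the excluded voxel
  exclude <- array(FALSE, c(6, 6, 6)); exclude[1, 1, 1] <- TRUE
  peaks <- clusterPeaks(tmap, mask, excludeMask = exclude)
  expect_identical(nrow(peaks), 1L)
  expect_identical(peaks$peakI, 2L)
  # fully excluded cluster reports an NA peak
  allEx <- clusterPeaks(tmap, mask, excludeMask = mask)
  expect_true(is.na(allEx$peakT))
})
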