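test_that("seed time course is the arithmetic mean over seed voxels", {
  scan <- noiseScan(c(3L, 3L, 3L, 12L))
  m <- array(FALSE, dim = c(3, 3, 3))

  m[2, 2, 2] <- TRUE
  expect_equal(extractSeedTimecourse(scan, seedMask("one", m)),
               mapData(scan)[2, 2, 2, ])

  # opposite series cancel
  d <- mapData(scan)
  d[1, 1, 1, ] <- d[2, 2, 2, ]
  d[3, 3, 3, ] <- -d[2, 2, 2, ]
  scan2 <- boldScan(d, mapAffine(scan), 3)
  m2 <- array(FALSE, dim = c(3, 3, 3)); m2[1, 1, 1] <- m2[3, 3, 3] <- TRUE
  expect_equal(extractSeedTimecourse(scan2, seedMask("pair", m2)),
               rep(0, 12))
})

test_that("averaging m noise voxels shrinks variance like 1/m", {
  set.seed(77)
  m <- array(FALSE, dim = c(4, 4, 4)); m[1:4, 1:4, 1] <- TRUE  # 16 voxels
  vs <- replicate(300, {
    scan <- boldScan(array(rnorm(4 * 4 * 4 * 20, sd = 2),
                           dim = c(4, 4, 4, 20)), gridAffine(), 3)
    var(extractSeedTimecourse(scan, seedMask("s", m)))
  })
  expect_equal(mean(vs), 4 / 16, tolerance = 0.1)
})

test_that("grid mismatch between seed and scan is an error", {
  scan <- noiseScan(c(4L, 4L, 4L, 12L))
  m <- array(TRUE, dim = c(3, 3, 3))
  expect_error(extractSeedTimecourse(scan, seedMask("bad", m)),
               "does not match")
  mOff <- array(TRUE, dim = c(4, 4, 4))
  expect_error(
    extractSeedTimecourse(scan, seedMask("bad", mOff, gridAffine(2))),
    "does not match")
})

test_that("r-map is exact on identical and sign-flipped voxel series", {
  scan <- noiseScan(c(3L, 3L, 3L, 30L), seed = 9L)
  tc <- mapData(scan)[1, 1, 1, ]
  d <- mapData(scan)
  d[3, 3, 3, ] <- -tc
  scan <- boldScan(d, mapAffine(scan), 3)
  rmap <- seedToVoxelRmap(scan, tc, "s")
  expect_equal(mapData(rmap)[1, 1, 1], 1)
  expect_equal(mapData(rmap)[3, 3, 3], -1)
  expect_true(all(mapData(rmap) >= -1 & mapData(rmap) <= 1))
  expect_equal(mapKind(rmap), "r")
})

test_that("zero-variance voxels give r = 0 with a QC count, never NaN", {
  d <- array(rnorm(3 * 3 * 3 * 12), dim = c(3, 3, 3, 12))
  d[2, 1, 1, ] <- 5   # constant voxel
  scan <- boldScan(d, gridAffine(), 3)
  rmap <- seedToVoxelRmap(scan, d[1, 1, 1, ])
  expect_true(all(is.finite(mapData(rmap))))
  expect_equal(mapData(rmap)[2, 1, 1], 0)
  expect_equal(qcFlags(rmap)$zero_variance_voxels, 1)
})

test_that("Fisher z is atanh with clamping at |r| = 1", {
  r <- array(c(0, 0.5, -0.5, 1, -1, 0.3, -0.3, 0.9), dim = c(2, 2, 2))
  z <- fisherZ(statMap("r", r))
  expect_equal(mapData(z)[1, 1, 1], 0)
  expect_equal(mapData(z)[2, 1, 1], 0.549306, tolerance = 1e-6)
  # antisymmetry over the value grid
  zv <- as.vector(mapData(z))
  expect_equal(zv[2], -zv[3])   # z(0.5) = -z(-0.5)
  expect_equal(zv[6], -zv[7])   # z(0.3) = -z(-0.3)
  expect_equal(zv[4], -zv[5])   # clamped pair at |r| = 1
  expect_true(all(is.finite(mapData(z))))
  expect_equal(qcFlags(z)$clamped_unit_r, 2)
  expect_equal(mapData(z)[2, 2, 1], atanh(1 - 1e-7))
})

test_that("group t-map matches the one-sample t definition", {
  mk <- function(vals) statMap("z", array(vals, dim = c(1, 1, 1)))
  expect_equal(mapData(groupTmap(list(mk(0), mk(0), mk(0))))[1, 1, 1], 0)
  expect_equal(mapData(groupTmap(list(mk(1), mk(-1))))[1, 1, 1], 0)

  tm <- groupTmap(list(mk(1), mk(1), mk(1)))
  expect_true(is.infinite(mapData(tm)[1, 1, 1]))
  expect_equal(qcFlags(tm)$infinite_t_voxels, 1)
  expect_equal(tm@df, 2)

  # analytic expectation: n = 1000 draws from N(0.3, 0.1^2) give
  # t ~ 0.3 / (0.1 / sqrt(1000)) = 94.9
  set.seed(13)
  zs <- rnorm(1000, mean = 0.3, sd = 0.1)
  tm2 <- groupTmap(lapply(zs, mk))
  expect_equal(mapData(tm2)[1, 1, 1],
               mean(zs) / (sd(zs) / sqrt(1000)))
  expect_equal(mapData(tm2)[1, 1, 1], 0.3 / (0.1 / sqrt(1000)),
               tolerance = 0.05)
  expect_equal(tm2@df, 999)
  expect_error(groupTmap(list(mk(1))), "at least 2")
})

test_that("Bonferroni t threshold matches the inverse t CDF", {
  expect_equal(bonferroniTThreshold(0.05, 1, 999), 1.962, tolerance = 1e-3)
  thr <- bonferroniTThreshold(0.05, 67000, 999)
  expect_gt(thr, 4.9); expect_lt(thr, 5.2)
  # limit: alpha near 1 with a single test sends the threshold to 0
  expect_lt(bonferroniTThreshold(0.999, 1, 50), 0.01)
  # the published |t| = 5.1 controls FWE at 0.05 over a 67k-voxel brain
  expect_lte(2 * pt(-5.1, df = 999) * 67000, 0.05)
})

test_that("binarization thresholds |t| and is monotone in the cutoff", {
  tvals <- array(0, dim = c(3, 3, 3))
  tvals[c(1, 5, 9, 14)] <- c(5.1, -6, 7.3, 5.2)   # 4 suprathreshold entries
  tvals[c(2, 3)] <- c(4.9, -5.0)
  tm <- statMap("t", tvals, df = 99)
  b <- thresholdBinarize(tm, 5.1)
  expect_equal(sum(mapData(b)), 4)
  expect_equal(qcFlags(b)$suprathreshold_voxels, 4)
  expect_true(all(mapData(b) %in% c(0, 1)))

  counts <- vapply(seq(0.5, 8, by = 0.5), function(thr)
    sum(mapData(thresholdBinarize(tm, thr))), 0)
  expect_true(all(diff(counts) <= 0))

  expect_equal(sum(mapData(thresholdBinarize(tm, 7.4))), 0)
  expect_error(thresholdBinarize(tm, 0), "tThreshold")
})

test_that("the map chain preserves grid shape and affine at every stage", {
  sp <- singleNetworkPhantom(4, rngSeed = 3, grid = c(6L, 6L, 6L),
                             nTimepoints = 20L)
  scans <- simulateBold(sp)
  seed <- phantomSeedMask(sp, "seed")
  aff <- mapAffine(scans[[1]])
  res <- seedConnectivityMap(scans, seed, analysisConfig(tThreshold = 3))
  for (m in list(res$tmap, res$binary)) {
    expect_equal(dim(mapData(m)), c(6L, 6L, 6L))
    expect_equal(mapAffine(m), aff)
  }
  expect_equal(res$tmap@df, 3)
  expect_equal(res$binary@sourceSeed, "seed")
})

test_that("average-r aggregation produces the mean r-map and a z statistic", {
  sp <- singleNetworkPhantom(6, rngSeed = 8, grid = c(6L, 6L, 6L),
                             nTimepoints = 24L)
  scans <- simulateBold(sp)
  seed <- phantomSeedMask(sp, "seed")
  res <- seedConnectivityMap(
    scans, seed, analysisConfig(rmapAggregation = "average_r"))
  expect_equal(mapKind(res$meanRmap), "r")
  expect_true(all(abs(mapData(res$meanRmap)) <= 1))
  expect_equal(res$tmap@df, 6 * (24 - 3))
  # each seed voxel correlates with the seed mean near 1/sqrt(2)
  expect_gt(mean(mapData(res$meanRmap)[regionMask(atlasFromSpec(sp),
                                                  "seed")]), 0.6)
})
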