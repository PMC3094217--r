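test_that("the speed image follows the piecewise-linear contract", {
  thr <- c(low = 90, high = 120)
  g <- matrix(c(80, 90, 105, 120, 130, 100), 2, 3)
  sp <- speedImage(g, thr)
  expect_equal(sp$P[g == 105], 15)                 # midpoint maximum
  expect_equal(sp$P[g == 90], 0)                   # zero at thresholds
  expect_equal(sp$P[g == 120], 0)
  expect_equal(sp$P[g == 80], -10)
  expect_equal(sp$P[g == 130], -10)
  # Z is the positive part scaled to [0, 1], zero where P <= 0
  expect_equal(max(sp$Z), 1)
  expect_equal(sp$Z[g == 80], 0)
  expect_true(all(sp$Z >= 0 & sp$Z <= 1))
  expect_error(speedImage(g, c(low = 5, high = 5)), "low < high")
})

test_that("a uniform disk is segmented from an interior seed", {
  n <- 80
  yy <- row(matrix(0, n, n)); xx <- col(matrix(0, n, n))
  disk <- (yy - 40)^2 + (xx - 40)^2 <= 25^2
  slice <- matrix(0, n, n); slice[disk] <- 100
  seed <- matrix(0L, n, n)
  seed[(yy - 40)^2 + (xx - 40)^2 <= 10^2] <- 1L
  res <- evolveSlice(slice, seed, levelSetParams())
  jac <- sum(res == 1 & disk) / sum(res == 1 | disk)
  expect_gte(jac, 0.95)
})

test_that("a seed over non-parenchyma intensities vanishes", {
  n <- 60
  slice <- matrix(0, n, n); slice[20:40, 20:40] <- 100
  seed <- matrix(0L, n, n); seed[45:55, 45:55] <- 1L
  # the running parenchyma model keeps thresholds around 100, so the seed
  # sits entirely on negative speed and must collapse
  res <- evolveSlice(slice, seed, levelSetParams(),
                     guardModel = gaussianModel(100, 100, 10))
  expect_equal(sum(res), 0)
})

test_that("curvature weight suppresses a one-voxel spur", {
  n <- 60
  yy <- row(matrix(0, n, n)); xx <- col(matrix(0, n, n))
  disk <- (yy - 30)^2 + (xx - 30)^2 <= 15^2
  slice <- matrix(0, n, n); slice[disk] <- 100
  slice[30, 45:55] <- 100                    # 1-voxel-wide spur
  seed <- matrix(0L, n, n)
  seed[(yy - 30)^2 + (xx - 30)^2 <= 14^2] <- 1L
  noCurv <- evolveSlice(slice, seed, levelSetParams(gamma = 0))
  withCurv <- evolveSlice(slice, seed, levelSetParams())  # gamma = 217.414
  spurIdx <- cbind(30, 50:55)
  expect_gt(sum(noCurv[spurIdx]), sum(withCurv[spurIdx]))
  expect_equal(sum(withCurv[spurIdx]), 0)
  boundaryLen <- function(m) sum(m & !(EBImage::erode(m,
    EBImage::makeBrush(3, "diamond")) == 1))
  expect_lte(boundaryLen(withCurv), boundaryLen(noCurv))
})

test_that("liver propagation reaches the spec'd overlap on a clean phantom", {
  ph <- noiselessPhantom()
  liver <- segmentedNoiselessLiver()
  jac <- jaccard(liver, ph$liver)
  voe <- 100 * (1 - jac)
  expect_lte(voe, 10)
  expect_gte(jac, 0.90)
  # iteration counts respect the cap
  iters <- attr(liver, "sliceIterations")
  expect_true(all(iters <= levelSetParams()@maxIterations))
})

test_that("fully interior structures are merged by hole filling, and no
           voxels appear beyond the vanish limit", {
  ph <- noiselessPhantom()
  liver <- segmentedNoiselessLiver()
  A <- voxelData(liver)
  nod <- voxelData(ph$nodules) == 1
  expect_gte(sum(A[nod]) / sum(nod), 0.95)
  ves <- voxelData(ph$vessels) == 1
  expect_gte(sum(A[ves]) / sum(ves), 0.9)
  # once a direction vanished no further slices carry liver
  zs <- which(apply(A != 0, 1, any))
  expect_equal(zs, seq(min(zs), max(zs)))
})

test_that("segmentation is equivariant to a global intensity shift", {
  ph <- smallPhantom(2, noiseSd = 0, confounder = FALSE)
  z <- midSlice(ph)
  init <- erodedInit(ph, z)
  p <- levelSetParams()
  a <- segmentLiver(ph$volume, z, init, p)
  shifted <- ctVolume(voxelData(ph$volume) + 25L,
                      spacing = voxelSpacing(ph$volume))
  b <- segmentLiver(shifted, z, init, p)
  expect_identical(voxelData(a), voxelData(b))
})

test_that("the peripheral dark nodule is not recovered (documented
           limitation)", {
  ph <- cached("peripheral1", makePhantom(phantomPreset("peripheral-nodule",
                                                        seed = 1)))
  z <- midSlice(ph)
  liver <- cached("peripheralSeg",
    segmentLiver(ph$volume, z, erodedInit(ph, z), levelSetParams()))
  A <- voxelData(liver)
  nod <- voxelData(ph$nodules) == 1
  expect_lt(sum(A[nod]) / sum(nod), 0.5)
})

test_that("input contract violations raise errors", {
  ph <- smallPhantom()
  expect_error(segmentLiver(ph$volume, 999, erodedInit(ph, midSlice(ph)),
                            levelSetParams()), "outside")
  empty <- matrix(0L, 64, 64)
  expect_error(segmentLiver(ph$volume, midSlice(ph), empty,
                            levelSetParams()), "empty")
  expect_error(evolveSlice(matrix(0, 4, 4), matrix(0L, 4, 4),
                           levelSetParams()), "empty")
})
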