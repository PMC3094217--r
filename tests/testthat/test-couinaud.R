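test_that("plane fitting is exact on noiseless planes and matches the
           normal-equations oracle under noise", {
  # points exactly on x = 5
  pts <- cbind(z = runif(50, 0, 10), y = runif(50, 0, 10), x = 5)
  p <- fitPlane(pts, "near_vertical")
  expect_equal(p@coefficients, c(0, 0, 5), tolerance = 1e-9)

  # points on z = 0.1 x + 2
  set.seed(3)
  pts2 <- cbind(z = 0, y = runif(60, 0, 20), x = runif(60, 0, 20))
  pts2[, "z"] <- 0.1 * pts2[, "x"] + 2
  p2 <- fitPlane(pts2, "near_horizontal")
  expect_equal(p2@coefficients, c(0.1, 0, 2), tolerance = 1e-9)

  # noisy fits agree with closed-form least squares, 10 seeds
  for (s in 1:10) {
    set.seed(100 + s)
    y <- runif(500, -20, 20); z <- runif(500, -30, 30)
    x <- 2 * y + 10 + rnorm(500, 0, 0.5)
    fit <- fitPlane(cbind(z = z, y = y, x = x), "near_vertical")
    oracle <- bruteLeastSquares(cbind(y, z, 1), x)
    expect_equal(fit@coefficients, as.numeric(oracle), tolerance = 1e-9)
    # coefficients near truth (a=2, b=0, c=10): crude 3-SE style bound
    expect_lt(abs(fit@coefficients[1] - 2), 0.01)
    expect_lt(abs(fit@coefficients[3] - 10), 0.3)
  }

  # refitting a plane on its own sampled points is idempotent
  grid <- as.matrix(expand.grid(z = seq(0, 30, 3), y = seq(0, 20, 2)))
  xs <- 0.3 * grid[, "y"] - 0.2 * grid[, "z"] + 7
  f1 <- fitPlane(cbind(z = grid[, "z"], y = grid[, "y"], x = xs),
                 "near_vertical")
  onPlane <- cbind(z = grid[, "z"], y = grid[, "y"],
                   x = f1@coefficients[1] * grid[, "y"] +
                       f1@coefficients[2] * grid[, "z"] + f1@coefficients[3])
  f2 <- fitPlane(onPlane, "near_vertical")
  expect_equal(f1@coefficients, f2@coefficients, tolerance = 1e-9)

  # rank-deficient geometry is refused
  degenerate <- cbind(z = 1:5, y = rep(2, 5), x = rep(3, 5))
  expect_error(fitPlane(degenerate, "near_horizontal"), "degenerate")
})

cubeLiver <- function() {
  # 100 mm cube sampled at 1 mm voxels, centres at 0.5 .. 99.5 mm so the
  # quarter planes split it into exact eighths
  voxelMask(array(1L, c(100, 100, 100)), spacing = c(1, 1, 1),
            origin = c(0.5, 0.5, 0.5))
}

vplane <- function(xc) new("PlaneModel", orientation = "near_vertical",
                           coefficients = c(0, 0, xc))
hplane <- function(zc) new("PlaneModel", orientation = "near_horizontal",
                           coefficients = c(0, 0, zc))

test_that("axis-aligned planes on a cube yield eight equal regions that
           partition it exactly", {
  liver <- cubeLiver()
  cm <- partitionCouinaud(liver, list(vplane(50), vplane(25), vplane(75)),
                          hplane(50))
  lab <- voxelData(cm)
  counts <- tabulate(lab[lab > 0], nbins = 8)
  expect_equal(sum(counts), maskVoxelCount(liver))
  expect_equal(length(unique(counts)), 1)      # 8 equal volumes
  expect_equal(length(unique(lab[lab > 0])), 8)
  expect_true(all(lab[voxelData(liver) == 1] > 0))
})

test_that("a liver entirely on one side of the portal plane leaves half the
           labels empty with a warning", {
  liver <- cubeLiver()
  expect_warning(
    cm <- partitionCouinaud(liver, list(vplane(25), vplane(50), vplane(75)),
                            hplane(-10)),
    "no voxels")
  lab <- voxelData(cm)
  expect_equal(length(unique(lab[lab > 0])), 4)
})

test_that("rigid translation leaves region volumes unchanged", {
  liver <- cubeLiver()
  planes <- list(vplane(30), vplane(55), vplane(80))
  cm1 <- partitionCouinaud(liver, planes, hplane(40))
  shift <- c(13, -7, 21)                      # (z, y, x) mm
  liver2 <- voxelMask(voxelData(liver), spacing = voxelSpacing(liver),
                      origin = voxelOrigin(liver) + shift)
  planes2 <- list(vplane(30 + shift[3]), vplane(55 + shift[3]),
                  vplane(80 + shift[3]))
  cm2 <- partitionCouinaud(liver2, planes2, hplane(40 + shift[1]))
  t1 <- tabulate(voxelData(cm1)[voxelData(cm1) > 0], 8)
  t2 <- tabulate(voxelData(cm2)[voxelData(cm2) > 0], 8)
  expect_equal(t1, t2)
})

test_that("the phantom pipeline produces exactly eight labelled regions", {
  res <- defaultPipelineRun()
  lab <- voxelData(res$couinaud$labels)
  inside <- lab[voxelData(res$liver) == 1]
  expect_equal(sort(unique(inside)), 1:8)
  # label partition covers the liver exactly
  expect_equal(sum(tabulate(inside, 8)), maskVoxelCount(res$liver))
  expect_true(all(lab[voxelData(res$liver) == 0] == 0))
})
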