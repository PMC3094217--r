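boxMask <- function(d, zr, yr, xr, spacing = c(1, 1, 1)) {
  a <- array(0L, d); a[zr, yr, xr] <- 1L
  voxelMask(a, spacing = spacing)
}

test_that("identical masks score perfectly on all five metrics", {
  m <- boxMask(c(14, 14, 14), 3:12, 3:12, 3:12)
  met <- computeMetrics(m, m)
  expect_equal(unname(met), c(0, 0, 0, 0, 0))
})

test_that("a shifted cube matches the brute-force oracle", {
  d <- c(18, 18, 18)
  ref <- boxMask(d, 4:13, 4:13, 4:13)
  seg <- boxMask(d, 4:13, 4:13, 7:16)        # 3-voxel shift along x
  met <- computeMetrics(seg, ref)
  oracle <- bruteMetrics(voxelData(seg), voxelData(ref), c(1, 1, 1))
  expect_equal(met[["voe"]], oracle[["voe"]], tolerance = 1e-12)
  expect_equal(met[["rvd"]], oracle[["rvd"]], tolerance = 1e-12)
  expect_equal(met[["asd"]], oracle[["asd"]], tolerance = 1e-9)
  expect_equal(met[["rmssd"]], oracle[["rmssd"]], tolerance = 1e-9)
  expect_equal(met[["msd"]], oracle[["msd"]], tolerance = 1e-9)
})

test_that("dilation gives positive volume difference and sub-diagonal ASD", {
  d <- c(16, 16, 16)
  ref <- boxMask(d, 5:11, 5:11, 5:11)
  seg <- boxMask(d, 4:12, 4:12, 4:12)
  met <- computeMetrics(seg, ref)
  oracle <- bruteMetrics(voxelData(seg), voxelData(ref), c(1, 1, 1))
  expect_gt(met[["rvd"]], 0)
  expect_lte(met[["asd"]], sqrt(3))
  expect_equal(unname(met), unname(oracle), tolerance = 1e-9)
})

test_that("metrics agree with the oracle on random mask pairs and keep the
           distance ordering", {
  set.seed(2024)
  for (trial in 1:50) {
    d <- c(12, 12, 12)
    spacing <- sample(list(c(1, 1, 1), c(2, 0.7, 0.7)), 1)[[1]]
    mk <- function() {
      a <- array(0L, d)
      n <- sample(1:3, 1)
      for (i in seq_len(n)) {
        z0 <- sample(1:8, 1); y0 <- sample(1:8, 1); x0 <- sample(1:8, 1)
        a[z0:(z0 + sample(2:4, 1)), y0:(y0 + sample(2:4, 1)),
          x0:(x0 + sample(2:4, 1))] <- 1L
      }
      a
    }
    refA <- mk(); segA <- mk()
    seg <- voxelMask(segA, spacing = spacing)
    ref <- voxelMask(refA, spacing = spacing)
    if (sum(segA) == 0 || sum(refA) == 0) next
    met <- computeMetrics(seg, ref)
    oracle <- bruteMetrics(segA, refA, spacing)
    expect_equal(met[["voe"]], oracle[["voe"]], tolerance = 1e-12)
    expect_equal(met[["rvd"]], oracle[["rvd"]], tolerance = 1e-12)
    expect_equal(met[["asd"]], oracle[["asd"]], tolerance = 1e-9)
    expect_equal(met[["rmssd"]], oracle[["rmssd"]], tolerance = 1e-9)
    expect_equal(met[["msd"]], oracle[["msd"]], tolerance = 1e-9)
    # max >= rms >= mean for any distance sample
    expect_gte(met[["msd"]], met[["rmssd"]] - 1e-12)
    expect_gte(met[["rmssd"]], met[["asd"]] - 1e-12)
    # symmetry of the surface distances; VOE symmetric, RVD sign flips
    rev <- computeMetrics(ref, seg)
    expect_equal(rev[["asd"]], met[["asd"]], tolerance = 1e-12)
    expect_equal(rev[["rmssd"]], met[["rmssd"]], tolerance = 1e-12)
    expect_equal(rev[["msd"]], met[["msd"]], tolerance = 1e-12)
    expect_equal(rev[["voe"]], met[["voe"]], tolerance = 1e-12)
    expect_equal((1 + rev[["rvd"]] / 100) * (1 + met[["rvd"]] / 100), 1,
                 tolerance = 1e-12)
  }
})

test_that("empty inputs are rejected with the documented semantics", {
  d <- c(8, 8, 8)
  full <- boxMask(d, 2:6, 2:6, 2:6)
  empty <- voxelMask(array(0L, d))
  expect_error(computeMetrics(full, empty), "empty reference")
  expect_error(computeMetrics(empty, full), "surface distances are undefined")
})

test_that("scoring is anchored at 100 for perfection and 75 at the human
           error, linear and clamped", {
  for (e in c(0.01, 1, 6.4, 250)) {
    expect_equal(scoreMetric(0, e), 100)
    expect_equal(scoreMetric(e, e), 75)
    expect_equal(scoreMetric(2 * e, e), 50)
    expect_equal(scoreMetric(4 * e, e), 0)
    expect_equal(scoreMetric(5 * e, e), 0)        # clamped
    expect_equal(scoreMetric(-e, e), 75)          # sign ignored (RVD)
  }
  expect_error(scoreMetric(1, 0), "positive")
})

test_that("the total score is the mean of the five metric scores", {
  refs <- humanErrorRefs(voe = 6.4, rvd = 4.7, asd = 1, rmssd = 1.8,
                         msd = 19)
  zero <- c(voe = 0, rvd = 0, asd = 0, rmssd = 0, msd = 0)
  expect_equal(totalScore(zero, refs)@totalScore, 100)
  atHuman <- c(voe = 6.4, rvd = 4.7, asd = 1, rmssd = 1.8, msd = 19)
  expect_equal(totalScore(atHuman, refs)@totalScore, 75)
  one2x <- c(voe = 12.8, rvd = 0, asd = 0, rmssd = 0, msd = 0)
  expect_equal(totalScore(one2x, refs)@totalScore, 90)  # (50 + 4*100)/5
  rep <- totalScore(atHuman, refs)
  expect_s4_class(rep, "MetricReport")
  expect_equal(unname(rep@scores), rep(75, 5))
})
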