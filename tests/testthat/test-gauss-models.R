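gauss <- function(x, K, mu, sigma) K * exp(-(x - mu)^2 / (2 * sigma^2))

test_that("Gaussian fitting recovers noiseless and noisy curves", {
  x <- 50:150
  h <- new("IntensityHistogram", mids = as.numeric(x),
           counts = gauss(x, 50, 100, 10))
  g <- fitGaussian(h)
  expect_equal(g@K, 50, tolerance = 1e-3)
  expect_equal(g@mu, 100, tolerance = 1e-3)
  expect_equal(g@sigma, 10, tolerance = 1e-3)

  # a symmetric histogram yields the symmetry centre as the mean
  hs <- new("IntensityHistogram", mids = as.numeric(80:120),
            counts = gauss(80:120, 30, 100, 6) + 5)
  expect_equal(fitGaussian(hs)@mu, 100, tolerance = 1e-6)

  # 5% uniform noise across 10 seeds: mean recovered within half a bin
  set.seed(99)
  for (s in 1:10) {
    noisy <- gauss(x, 50, 100, 10) + runif(length(x), 0, 0.05 * 50)
    gn <- fitGaussian(new("IntensityHistogram", mids = as.numeric(x),
                          counts = noisy))
    expect_lte(abs(gn@mu - 100), 0.5)
  }

  # collapsed histogram: flagged, sigma floored
  hd <- new("IntensityHistogram", mids = as.numeric(1:11),
            counts = c(rep(0, 5), 40, rep(0, 5)))
  gd <- fitGaussian(hd)
  expect_equal(gd@flag, "degenerate")
  expect_gt(gd@sigma, 0)
})

test_that("threshold inversion matches the closed form and the forward
           evaluation", {
  g <- gaussianModel(50, 100, 10)
  thr <- thresholdsFromGaussian(g, 0.5, 0.5)
  expect_equal(unname(thr), c(88.22592, 111.77408), tolerance = 1e-4)

  # forward evaluation of the unit-amplitude Gaussian reproduces the factors
  for (gl in c(0.1, 0.2809, 0.3859, 0.9)) {
    for (gh in c(0.15, 0.2809, 0.7)) {
      t2 <- thresholdsFromGaussian(g, gl, gh)
      expect_equal(gaussianValue(g, t2[["low"]], unitAmplitude = TRUE), gl,
                   tolerance = 1e-9)
      expect_equal(gaussianValue(g, t2[["high"]], unitAmplitude = TRUE), gh,
                   tolerance = 1e-9)
    }
  }

  # the tuned factors on a standard Gaussian
  t3 <- thresholdsFromGaussian(gaussianModel(1, 0, 1), 0.3859, 0.2809)
  expect_equal(t3[["low"]], -sqrt(-2 * log(0.3859)), tolerance = 1e-9)
  expect_equal(t3[["high"]], sqrt(-2 * log(0.2809)), tolerance = 1e-9)

  # near-unity factors collapse both thresholds to the mean
  t4 <- thresholdsFromGaussian(g, 1 - 1e-12, 1 - 1e-12)
  expect_equal(unname(t4), c(100, 100), tolerance = 1e-4)
  expect_error(thresholdsFromGaussian(g, 0, 0.5), "inside")
})

mixCounts <- function(x) {
  gauss(x, 2000, 100, 12) + gauss(x, 150, 40, 8) + gauss(x, 300, 160, 9)
}

test_that("mixture decomposition recovers a noiseless three-class histogram", {
  x <- as.numeric(0:220)
  m <- decomposeMixture(new("IntensityHistogram", mids = x,
                            counts = mixCounts(x)))
  expect_lte(abs(mixtureComponent(m, "left")@mu - 40), 1)
  expect_lte(abs(mixtureComponent(m, "centre")@mu - 100), 1)
  expect_lte(abs(mixtureComponent(m, "right")@mu - 160), 1)
  expect_true(m@left@mu < m@centre@mu && m@centre@mu < m@right@mu)
})

test_that("mixture decomposition is robust to multinomial sampling noise", {
  x <- as.numeric(0:220)
  p <- mixCounts(x) / sum(mixCounts(x))
  set.seed(7)
  for (s in 1:10) {
    counts <- as.numeric(rmultinom(1, 200000, p))
    m <- decomposeMixture(new("IntensityHistogram", mids = x,
                              counts = counts))
    expect_lte(abs(mixtureComponent(m, "centre")@mu - 100), 1)
    expect_lte(abs(mixtureComponent(m, "left")@mu - 40), 3)
    expect_lte(abs(mixtureComponent(m, "right")@mu - 160), 3)
  }
})

test_that("a pure Gaussian yields absent side components", {
  x <- as.numeric(50:150)
  m <- decomposeMixture(new("IntensityHistogram", mids = x,
                            counts = gauss(x, 2000, 100, 12)))
  expect_equal(m@left@flag, "absent")
  expect_equal(m@right@flag, "absent")
  expect_lte(abs(m@centre@mu - 100), 0.5)
})

test_that("decomposition commutes with intensity shifts", {
  x <- as.numeric(0:220)
  m0 <- decomposeMixture(new("IntensityHistogram", mids = x,
                             counts = mixCounts(x)))
  m1 <- decomposeMixture(new("IntensityHistogram", mids = x + 37,
                             counts = mixCounts(x)))
  expect_equal(m1@left@mu - m0@left@mu, 37, tolerance = 1e-6)
  expect_equal(m1@centre@mu - m0@centre@mu, 37, tolerance = 1e-6)
  expect_equal(m1@right@mu - m0@right@mu, 37, tolerance = 1e-6)
})

test_that("growing thresholds match symmetry and a grid-scan oracle", {
  # equal amplitude, equal sigma: intersection at the midpoint of the means
  m <- mixtureModel(gaussianModel(100, 40, 10), gaussianModel(100, 100, 10),
                    gaussianModel(100, 160, 10))
  thrR <- growThresholds(m, "right")
  expect_equal(thrR[["low"]], 130, tolerance = 1e-3)
  # proportion -> 0.5 collapses the seed threshold onto the intersection
  thrR2 <- growThresholds(m, "right", proportion = 0.5 + 1e-9)
  expect_equal(thrR2[["high"]], 130, tolerance = 0.01)

  # grid-scan oracle on an asymmetric pair
  gl <- gaussianModel(150, 40, 8); gc <- gaussianModel(2000, 100, 12)
  m2 <- mixtureModel(gl, gc, gaussianModel(300, 160, 9))
  thr <- growThresholds(m2, "left", 0.70)
  xs <- seq(0, 100, by = 0.01)
  share <- gaussianValue(gl, xs) / (gaussianValue(gl, xs) +
                                    gaussianValue(gc, xs))
  oracleLow <- max(xs[share >= 0.70])
  dif <- abs(gaussianValue(gl, xs) - gaussianValue(gc, xs))
  between <- xs > 40 & xs < 100
  oracleHigh <- xs[between][which.min(dif[between])]
  expect_equal(thr[["low"]], oracleLow, tolerance = 0.02)
  expect_equal(thr[["high"]], oracleHigh, tolerance = 0.02)
  expect_lt(thr[["low"]], thr[["high"]])

  # identical means admit no intersection between the means
  bad <- mixtureModel(gaussianModel(10, 100 - 1e-13, 5),
                      gaussianModel(100, 100, 10),
                      gaussianModel(10, 160, 5))
  expect_error(growThresholds(bad, "left"), "degenerac")
})
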