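# Shared fixtures and independent oracles. Expensive phantom runs are
# memoized for the duration of the test session.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- force(expr)
  .fixtureCache[[key]]
}

defaultPhantom <- function(seed = 1)
  cached(paste0("default", seed), makePhantom(phantomPreset("default", seed)))

noiselessPhantom <- function(seed = 1)
  cached(paste0("clean", seed),
         makePhantom(phantomSpec(seed = seed, noiseSd = 0,
                                 confounder = FALSE)))

smallPhantom <- function(seed = 1, ...)
  cached(paste0("small", seed, paste(c(...), collapse = "_")),
         makePhantom(phantomSpec(shape = c(48, 64, 64), seed = seed, ...)))

# 60%-area eroded true liver cross-section: the manual initial solution
erodedInit <- function(ph, z) {
  truth <- voxelData(ph$liver)[z, , ]
  target <- 0.6 * sum(truth)
  er <- truth
  b <- EBImage::makeBrush(3, "box")
  while (sum(er) > target) er <- EBImage::erode(er, b)
  matrix(as.integer(er), nrow(truth), ncol(truth))
}

midSlice <- function(ph) (dim(voxelData(ph$volume))[1] + 1) %/% 2

segmentedNoiselessLiver <- function() {
  cached("cleanLiverSeg", {
    ph <- noiselessPhantom()
    z <- midSlice(ph)
    segmentLiver(ph$volume, z, erodedInit(ph, z), levelSetParams())
  })
}

defaultPipelineRun <- function() {
  cached("defaultPipeline", {
    ph <- defaultPhantom()
    z <- midSlice(ph)
    runPipeline(ph$volume, z, erodedInit(ph, z))
  })
}

# 6-neighbour erosion, used to strip a mask's partial-volume boundary shell
erodeMask <- function(m, n = 2) {
  a <- voxelData(m) != 0
  sh <- hepatoseg:::shift3
  for (i in seq_len(n))
    a <- a & sh(a, 1, 0, 0) & sh(a, -1, 0, 0) & sh(a, 0, 1, 0) &
         sh(a, 0, -1, 0) & sh(a, 0, 0, 1) & sh(a, 0, 0, -1)
  voxelMask(array(as.integer(a), dim(a)), like = m)
}

jaccard <- function(a, b) {
  A <- voxelData(a) != 0; B <- voxelData(b) != 0
  sum(A & B) / sum(A | B)
}

dice <- function(a, b) {
  A <- voxelData(a) != 0; B <- voxelData(b) != 0
  2 * sum(A & B) / (sum(A) + sum(B))
}

# --- independent oracles -----------------------------------------------------

# brute-force disparity metrics: explicit 6-neighbour border extraction and
# a full double loop over border voxel pairs (Euclidean, mm)
bruteMetrics <- function(segArr, refArr, spacing) {
  stopifnot(identical(dim(segArr), dim(refArr)))
  d <- dim(segArr)
  isBorder <- function(m) {
    out <- array(FALSE, d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (m[i, j, k] == 0) next
      nb <- c(
        if (i > 1) m[i - 1, j, k] else 0, if (i < d[1]) m[i + 1, j, k] else 0,
        if (j > 1) m[i, j - 1, k] else 0, if (j < d[2]) m[i, j + 1, k] else 0,
        if (k > 1) m[i, j, k - 1] else 0, if (k < d[3]) m[i, j, k + 1] else 0)
      if (any(nb == 0) || i == 1 || i == d[1] || j == 1 || j == d[2] ||
          k == 1 || k == d[3]) out[i, j, k] <- TRUE
    }
    out
  }
  coords <- function(b) {
    ai <- which(b, arr.ind = TRUE)
    sweep(ai - 1, 2, spacing, "*")
  }
  bs <- coords(isBorder(segArr)); br <- coords(isBorder(refArr))
  oneWay <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i)
      sqrt(min(colSums((t(b) - a[i, ])^2))), 0)
  }
  dists <- c(oneWay(bs, br), oneWay(br, bs))
  nI <- sum(segArr != 0 & refArr != 0); nU <- sum(segArr != 0 | refArr != 0)
  c(voe = 100 * (1 - nI / nU),
    rvd = 100 * (sum(segArr != 0) - sum(refArr != 0)) / sum(refArr != 0),
    asd = mean(dists), rmssd = sqrt(mean(dists^2)), msd = max(dists))
}

# plain breadth-first flood fill with an explicit queue
bruteFlood <- function(accept, seeds, connectivity = 26L) {
  d <- dim(accept)
  offs <- if (connectivity == 6L) {
    matrix(c(-1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1),
           ncol = 3, byrow = TRUE)
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, ]
  }
  visited <- array(FALSE, d)
  queue <- which(accept[seeds] != 0)
  queue <- seeds[queue]
  visited[queue] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    ci <- arrayInd(cur, d)
    for (r in seq_len(nrow(offs))) {
      ni <- ci + offs[r, ]
      if (any(ni < 1) || any(ni > d)) next
      lin <- ni[1] + (ni[2] - 1) * d[1] + (ni[3] - 1) * d[1] * d[2]
      if (accept[lin] != 0 && !visited[lin]) {
        visited[lin] <- TRUE
        queue <- c(queue, lin)
      }
    }
  }
  array(as.integer(visited), d)
}

# closed-form least squares through the normal equations
bruteLeastSquares <- function(X, y) solve(t(X) %*% X, t(X) %*% y)
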