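# small constructed vessel scenes on a common grid
tubeScene <- function(d = c(60, 40, 40), liverZ = 5:56) {
  liver <- array(0L, d)
  liver[liverZ, 5:36, 5:36] <- 1L
  list(d = d, liver = voxelMask(liver, spacing = c(2, 1, 1)))
}

addTube <- function(arr, z, y, x, r = 1.6) {
  for (zz in z) {
    sl <- (row(matrix(0, dim(arr)[2], dim(arr)[3])) - y)^2 +
          (col(matrix(0, dim(arr)[2], dim(arr)[3])) - x)^2 <= r^2
    arr[zz, , ][sl] <- 1L
  }
  arr
}

test_that("branch tracking accepts tall tubes and rejects short blobs", {
  sc <- tubeScene()
  v <- array(0L, sc$d)
  v <- addTube(v, 25:52, 20, 10)
  v <- addTube(v, 25:52, 20, 20)
  v <- addTube(v, 25:52, 20, 30)
  v <- addTube(v, 12:13, 12, 14)           # ~4% of liver height
  v <- addTube(v, 15:16, 28, 26)
  vessels <- voxelMask(v, spacing = c(2, 1, 1))
  br <- trackMainBranches(vessels, sc$liver)
  expect_length(br, 3)
  # short blobs excluded from every accepted branch
  blobIdx <- which(addTube(addTube(array(0L, sc$d), 12:13, 12, 14),
                           15:16, 28, 26) == 1)
  for (b in br) expect_equal(sum(voxelData(b)[blobIdx]), 0)
})

test_that("a single short tube yields no accepted branch, flagged", {
  sc <- tubeScene()
  v <- addTube(array(0L, sc$d), 30:34, 20, 20)  # ~10% of liver height
  br <- trackMainBranches(voxelMask(v, spacing = c(2, 1, 1)), sc$liver)
  expect_length(br, 0)
  expect_equal(attr(br, "flag"), "fewer branches than expected")
})

test_that("a Y-shaped merge is absorbed into one candidate", {
  sc <- tubeScene()
  v <- array(0L, sc$d)
  v <- addTube(v, 40:52, 20, 14)            # long left arm of the Y
  v <- addTube(v, 48:52, 20, 18)            # short second arm (~10%)
  # arms join: bridge at the merge slice, then a common trunk
  v[48, 20, 14:18] <- 1L
  v <- addTube(v, 20:47, 20, 14)            # trunk continues from arm 1
  br <- trackMainBranches(voxelMask(v, spacing = c(2, 1, 1)), sc$liver)
  expect_length(br, 1)
  expect_equal(attr(br, "flag"), "fewer branches than expected")
  # the accepted branch contains the trunk
  expect_gt(sum(voxelData(br[[1]])[20:47, , ]), 0)
})

test_that("clock labelling orders branches right, middle, left", {
  d <- c(30, 40, 80)
  mk <- function(x) {
    a <- array(0L, d); a[14:16, 19:21, (x - 1):(x + 1)] <- 1L
    voxelMask(a, spacing = c(1, 1, 1))
  }
  center <- c(40, 5)                        # (x, z) mm; branches lie above
  # patient right at negative displacement: x=10 -> right, 40 -> middle
  labs <- classifyClockwise(list(mk(10), mk(40), mk(70)), center = center)
  expect_equal(labs, c("right", "middle", "left"))
  # permutation equivariance
  labs2 <- classifyClockwise(list(mk(70), mk(10), mk(40)), center = center)
  expect_equal(labs2, c("left", "right", "middle"))
  # a single branch gets the first clockwise label; the rest are missing
  labs3 <- classifyClockwise(list(mk(10)), center = center)
  expect_equal(as.vector(labs3), "right")
  expect_setequal(attr(labs3, "missing"), c("middle", "left"))
  expect_error(classifyClockwise(list(mk(10), mk(10)), center = center),
               "tie")
})

test_that("portal extraction conserves vessel voxels and merges touching
           residuals", {
  sc <- tubeScene()
  v <- array(0L, sc$d)
  v <- addTube(v, 25:52, 20, 10)
  v <- addTube(v, 25:52, 20, 20)
  v <- addTube(v, 25:52, 20, 30)
  # horizontal trunk (the portal): largest residual
  v[18:20, 18:22, 8:32] <- 1L
  # residual fragment touching the middle tube at its flank
  v[30:31, 22:23, 20] <- 1L
  # far-away floater -> auxiliary
  v[10, 30, 10] <- 1L
  vessels <- voxelMask(v, spacing = c(2, 1, 1))
  br <- trackMainBranches(vessels, sc$liver)
  expect_length(br, 3)
  pe <- extractPortal(vessels, br)
  # conservation: branches + portal + auxiliary == vessels, exactly
  un <- voxelData(pe$portal) | voxelData(pe$auxiliary)
  for (b in pe$branches) un <- un | voxelData(b)
  expect_identical(array(as.integer(un), sc$d), v)
  expect_equal(voxelData(pe$portal)[19, 19, 10], 1L)
  expect_equal(voxelData(pe$auxiliary)[10, 30, 10], 1L)
  # the touching fragment was merged into a branch, not auxiliary
  expect_equal(voxelData(pe$auxiliary)[30, 22, 20], 0L)
  expect_equal(voxelData(pe$portal)[30, 22, 20], 0L)

  # no residuals at all -> empty flagged portal
  justTubes <- array(0L, sc$d)
  justTubes <- addTube(justTubes, 25:52, 20, 10)
  jt <- voxelMask(justTubes, spacing = c(2, 1, 1))
  br1 <- trackMainBranches(jt, sc$liver, nBranches = 1L)
  pe2 <- extractPortal(jt, br1)
  expect_equal(maskVoxelCount(pe2$portal), 0)
  expect_match(attr(pe2$portal, "flag"), "no vessels left")
})

test_that("phantom vein identification matches the generator's labels
           across seeds", {
  for (s in 1:10) {
    ph <- makePhantom(phantomSpec(shape = c(48, 64, 64), seed = s))
    veins <- identifyVeins(ph$vessels, ph$liver)
    expect_setequal(veins$labels, c("right", "middle", "left"))
    hb <- voxelData(ph$hepaticBranches)
    truthCode <- c(right = 1L, middle = 2L, left = 3L)
    for (nm in names(veins$branches)) {
      b <- voxelData(veins$branches[[nm]]) != 0 & hb > 0
      # the dominant truth label under each branch matches its name
      expect_equal(unname(which.max(tabulate(hb[b], 3))),
                   unname(truthCode[[nm]]))
    }
    # portal recovered as the biggest residual component
    expect_gte(dice(veins$portal, ph$portal), 0.95)
  }
})
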