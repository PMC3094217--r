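## Seeded synthetic CT liver phantom.
##
## The generator encodes the two working hypotheses of the pipeline: the
## liver parenchyma is roughly homogeneous (near-Gaussian intensities) and
## the liver veins lie mainly inside the liver. The phantom is an
## ellipsoid-like liver blob with three near-vertical bright hepatic tubes
## converging superiorly, one near-horizontal bright portal trunk entering
## mid-liver, dark spherical adipose nodules, short bright distractor blobs
## (auxiliary vessels), and an optional adjacent confounder blob with
## overlapping intensities. All geometry is expressed in fractions of the
## liver semi-axes so the same anatomy scales to smaller grids.

#' Phantom specification
#'
#' Defaults reproduce the intensity ordering the segmentation method assumes
#' (vessels brighter than parenchyma, adipose nodules darker): parenchyma
#' 100 +/- 15, vessels 160 +/- 10, nodules 40 +/- 10, background 0,
#' confounder blob 95 +/- 15, in arbitrary CT-like integer units.
#'
#' @param shape grid shape (nz, ny, nx), each >= 16.
#' @param spacing voxel spacing (sz, sy, sx) in mm.
#' @param parenchymaMean,parenchymaSd liver parenchyma intensity law.
#' @param vesselMean,vesselSd vessel intensity law (mean must exceed
#'   `parenchymaMean`).
#' @param noduleMean,noduleSd nodule intensity law (mean must be below
#'   `parenchymaMean`).
#' @param nNodules number of dark nodules (0..4 placement slots).
#' @param nHepaticBranches number of tall hepatic tubes (0..3).
#' @param branchHeightFraction fraction of the liver height spanned by the
#'   hepatic tubes (default 0.45, well above the 0.15 acceptance rule).
#' @param nDistractors short bright blobs (~5\% of liver height) that must be
#'   rejected by branch tracking.
#' @param confounder place an adjacent iso-intense blob next to the liver.
#' @param confounderMean,confounderSd,confounderGap confounder intensity law
#'   and gap (voxels of background) between blob and liver; a gap of 0 makes
#'   the blob touch the liver.
#' @param noduleStyle `"interior"` (default), `"big"` (single nodule with
#'   volume comparable to the parenchyma, which breaks the Gaussian
#'   histogram assumption) or `"peripheral"` (single nodule straddling the
#'   liver boundary, which hole filling cannot recover).
#' @param noiseSd additive Gaussian noise applied to the whole volume.
#' @param seed RNG seed; the phantom is a deterministic function of the spec.
#' @return A validated list of class `"phantomSpec"`.
#' @export
phantomSpec <- function(shape = c(96, 128, 128), spacing = c(2, 1, 1),
                        parenchymaMean = 100, parenchymaSd = 15,
                        vesselMean = 160, vesselSd = 10,
                        noduleMean = 40, noduleSd = 10,
                        nNodules = 2, nHepaticBranches = 3,
                        branchHeightFraction = 0.45, nDistractors = 2,
                        confounder = TRUE, confounderMean = 95,
                        confounderSd = 15, confounderGap = 3,
                        noduleStyle = c("interior", "big", "peripheral"),
                        noiseSd = 2, seed = 1) {
  noduleStyle <- match.arg(noduleStyle)
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               parenchymaMean = parenchymaMean, parenchymaSd = parenchymaSd,
               vesselMean = vesselMean, vesselSd = vesselSd,
               noduleMean = noduleMean, noduleSd = noduleSd,
               nNodules = as.integer(nNodules),
               nHepaticBranches = as.integer(nHepaticBranches),
               branchHeightFraction = branchHeightFraction,
               nDistractors = as.integer(nDistractors),
               confounder = isTRUE(confounder),
               confounderMean = confounderMean, confounderSd = confounderSd,
               confounderGap = confounderGap, noduleStyle = noduleStyle,
               noiseSd = noiseSd, seed = as.integer(seed))
  if (any(spec$shape < 16L)) stop("phantom spec error: shape components must be >= 16")
  if (length(spec$spacing) != 3 || any(spec$spacing <= 0))
    stop("phantom spec error: spacing must be 3 positive values")
  if (!(vesselMean > parenchymaMean && parenchymaMean > noduleMean))
    stop("phantom spec error: need vesselMean > parenchymaMean > noduleMean")
  if (any(c(parenchymaSd, vesselSd, noduleSd, noiseSd) < 0))
    stop("phantom spec error: standard deviations must be >= 0")
  if (spec$nNodules < 0L ||
      (noduleStyle == "interior" && spec$nNodules > 4L) ||
      (noduleStyle != "interior" && spec$nNodules > 1L))
    stop("phantom spec error: cannot place that many nodules in the liver")
  if (spec$nHepaticBranches < 0L || spec$nHepaticBranches > 3L)
    stop("phantom spec error: nHepaticBranches must be 0..3")
  if (branchHeightFraction <= 0 || branchHeightFraction > 0.85)
    stop("phantom spec error: branchHeightFraction must be in (0, 0.85]")
  class(spec) <- "phantomSpec"
  spec
}

#' Phantom presets
#'
#' `"default"` is the standard study phantom. `"big-nodule"` and
#' `"peripheral-nodule"` are stress presets reproducing the two documented
#' failure modes of the Gaussian-parenchyma heuristic: a nodule of volume
#' comparable to the parenchyma distorts the histogram and the fitted
#' thresholds admit an adjacent darker structure (leak); a dark nodule at
#' the liver periphery falls outside the parenchyma intensity range and,
#' not being fully enclosed, cannot be recovered by hole filling.
#'
#' @param preset preset name.
#' @param seed RNG seed forwarded to [phantomSpec()].
#' @param shape optional grid shape override.
#' @return A `"phantomSpec"`.
#' @export
phantomPreset <- function(preset = c("default", "big-nodule",
                                     "peripheral-nodule"),
                          seed = 1, shape = c(96, 128, 128)) {
  preset <- match.arg(preset)
  switch(preset,
    "default" = phantomSpec(seed = seed, shape = shape),
    "big-nodule" = phantomSpec(seed = seed, shape = shape,
      noduleStyle = "big", nNodules = 1, noduleMean = 60, noduleSd = 15,
      confounder = TRUE, confounderMean = 70, confounderSd = 8,
      confounderGap = 0),
    "peripheral-nodule" = phantomSpec(seed = seed, shape = shape,
      noduleStyle = "peripheral", nNodules = 1))
}

# ellipsoid membership helper on precomputed voxel coordinate grids
ellipsoidMask <- function(Z, Y, X, center, radii) {
  ((Z - center[1]) / radii[1])^2 + ((Y - center[2]) / radii[2])^2 +
    ((X - center[3]) / radii[3])^2 <= 1
}

#' Generate a phantom with ground truth
#'
#' @param spec a [phantomSpec()].
#' @return A list of class `"phantomTruth"` with elements `volume`
#'   ([CTVolume-class], integer intensities), `liver`, `vessels`, `nodules`,
#'   `portal`, `confounder` ([VoxelMask-class]) and `hepaticBranches`
#'   ([LabelVolume-class] labelled right/middle/left), plus the `spec`.
#'   Vessels and nodules lie inside the liver (except the peripheral-nodule
#'   stress preset); branch labels are pairwise disjoint.
#' @examples
#' ph <- makePhantom(phantomSpec(shape = c(24, 32, 32), nNodules = 0,
#'                               nDistractors = 0, seed = 7))
#' ph$liver
#' @export
makePhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  d <- spec$shape
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  zc <- (nz + 1) / 2; yc <- (ny + 1) / 2; xc <- (nx + 1) / 2
  Z <- array(rep(seq_len(nz), times = ny * nx), d)
  Y <- array(rep(rep(seq_len(ny), each = nz), times = nx), d)
  X <- array(rep(seq_len(nx), each = nz * ny), d)

  az <- 0.54 * nz / 2; ay <- 0.59 * ny / 2; ax <- 0.66 * nx / 2
  liver <- ellipsoidMask(Z, Y, X, c(zc, yc, xc), c(az, ay, ax))

  ## hepatic tubes: near-vertical, converging toward the superior end
  tubeR <- max(2.2, 0.060 * ax)
  zTop <- zc + 0.85 * az
  zBot <- zTop - spec$branchHeightFraction * 2 * az
  # (bottom x offset, top x offset, y offset) per branch, fractions of axes;
  # patient right is negative x
  tubeDef <- list(right  = c(-0.62, -0.29,  0.10),
                  middle = c( 0.00,  0.00, -0.16),
                  left   = c( 0.62,  0.29,  0.10))
  branches <- array(0L, d)
  zSlices <- max(1, ceiling(zBot)):min(nz, floor(zTop))
  for (b in seq_len(spec$nHepaticBranches)) {
    def <- tubeDef[[b]]
    for (z in zSlices) {
      f <- (z - zBot) / (zTop - zBot)
      x0 <- xc + (def[1] + f * (def[2] - def[1])) * ax
      y0 <- yc + def[3] * ay
      sl <- (matrix(seq_len(ny), ny, nx) - y0)^2 +
            (matrix(seq_len(nx), ny, nx, byrow = TRUE) - x0)^2 <= tubeR^2
      plane <- branches[z, , ]
      plane[sl & liver[z, , ]] <- b
      branches[z, , ] <- plane
    }
  }

  ## portal trunk: near-horizontal, entering mid-liver below the tubes
  portal <- array(FALSE, d)
  portalR <- max(2.2, 0.083 * ax)
  xRange <- seq(floor(xc - 0.71 * ax), ceiling(xc + 0.71 * ax))
  for (x in xRange) {
    z0 <- zc - 0.35 * az + 0.05 * (x - xc)
    y0 <- yc
    sl <- (matrix(seq_len(nz), nz, ny) - z0)^2 +
          (matrix(seq_len(ny), nz, ny, byrow = TRUE) - y0)^2 <= portalR^2
    plane <- portal[, , x]
    portal[, , x] <- plane | (sl & liver[, , x])
  }

  ## short bright distractor blobs (~5% of liver height)
  distract <- array(FALSE, d)
  distractDef <- list(c(-0.38, -0.37,  0.71), c(-0.38, 0.37, -0.71))
  for (k in seq_len(spec$nDistractors)) {
    def <- distractDef[[((k - 1) %% 2) + 1]]
    ctr <- c(zc + def[1] * az, yc + def[2] * ay, xc + def[3] * ax)
    distract <- distract |
      (ellipsoidMask(Z, Y, X, ctr, c(0.05 * 2 * az / 2, tubeR, tubeR)) & liver)
  }

  ## nodules
  sz <- spec$spacing
  nodules <- array(FALSE, d)
  if (spec$nNodules > 0L) {
    if (spec$noduleStyle == "interior") {
      pos <- list(c(-0.31, -0.39,  0.48, 8), c(0.23,  0.47, -0.43, 7),
                  c( 0.55, -0.20,  0.15, 6), c(-0.10, 0.15, -0.65, 6))
      for (k in seq_len(spec$nNodules)) {
        p <- pos[[k]]
        ctr <- c(zc + p[1] * az, yc + p[2] * ay, xc + p[3] * ax)
        nodules <- nodules |
          ellipsoidMask(Z, Y, X, ctr, p[4] * min(ax / 42, 1) / sz)
      }
      nodules <- nodules & liver
    } else if (spec$noduleStyle == "big") {
      ctr <- c(zc, yc - 0.21 * ay, xc - 0.24 * ax)
      nodules <- ellipsoidMask(Z, Y, X, ctr,
                               c(0.69 * az, 0.68 * ay, 0.67 * ax)) & liver
    } else {  # peripheral: straddles the boundary; liver includes the bump
      ctr <- c(zc, yc, xc + ax)
      nodules <- ellipsoidMask(Z, Y, X, ctr, 10 * min(ax / 42, 1) / sz)
      liver <- liver | nodules
    }
  }

  ## confounder blob, patient-right of the liver, separated by a gap
  confound <- array(FALSE, d)
  if (spec$confounder) {
    crx <- 0.19 * ax
    ctr <- c(zc, yc, xc - (ax + spec$confounderGap + crx))
    confound <- ellipsoidMask(Z, Y, X, ctr, c(0.38 * az, 0.37 * ay, crx)) &
      !liver
  }

  vessels <- (branches > 0L) | portal | distract
  nodules <- nodules & !vessels

  ## draw intensities deterministically from the seed
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  ## Class intensities are drawn white, then an in-plane blur emulates the
  ## reconstruction point-spread function: CT intensities are never
  ## voxelwise independent, and partial-volume edges are what stops a
  ## threshold-driven contour cleanly. The draw widths are inflated by the
  ## kernel's white-noise attenuation (1/0.643 for the sigma-0.5 kernel) so
  ## that the observable post-blur voxel distributions match the spec'd
  ## class laws.
  psfSigma <- 0.5
  inflate <- 1 / 0.6434
  vol <- array(0, d)
  paren <- liver & !vessels & !nodules
  vol[paren] <- rnorm(sum(paren), spec$parenchymaMean,
                      inflate * spec$parenchymaSd)
  vol[nodules] <- rnorm(sum(nodules), spec$noduleMean,
                        inflate * spec$noduleSd)
  vol[vessels] <- rnorm(sum(vessels), spec$vesselMean,
                        inflate * spec$vesselSd)
  if (spec$confounder)
    vol[confound] <- rnorm(sum(confound), spec$confounderMean,
                           inflate * spec$confounderSd)
  for (z in seq_len(nz))
    vol[z, , ] <- EBImage::gblur(vol[z, , ], sigma = psfSigma)
  if (spec$noiseSd > 0)
    vol <- vol + rnorm(length(vol), 0, spec$noiseSd)
  vol <- array(as.integer(round(vol)), d)

  mk <- function(m) voxelMask(array(as.integer(m), d), spacing = sz)
  structure(list(
    volume = ctVolume(vol, spacing = sz),
    liver = mk(liver),
    vessels = mk(vessels),
    nodules = mk(nodules),
    portal = mk(portal),
    confounder = mk(confound),
    hepaticBranches = labelVolume(
      array(as.integer(branches), d),
      legend = c("1" = "right", "2" = "middle", "3" = "left"),
      spacing = sz),
    spec = spec), class = "phantomTruth")
}

#' Intensity histogram of a masked region
#'
#' Counts over contiguous equal-width bins covering the masked intensity
#' range; counts always sum to the number of masked voxels. Bin width
#' defaults to 1 intensity unit (CT-like integer data).
#'
#' @param volume a [CTVolume-class].
#' @param mask a [VoxelMask-class] on the same grid; must be nonempty.
#' @param binWidth bin width in intensity units.
#' @return An [IntensityHistogram-class].
#' @export
intensityHistogram <- function(volume, mask, binWidth = 1) {
  stopIfGeometryDiffers(volume, mask)
  v <- voxelData(volume)[voxelData(mask) != 0]
  if (!length(v)) stop("empty mask: cannot build an intensity histogram")
  # bins centered on multiples of binWidth, so integer CT data with the
  # default width lands on integer bin centers
  k <- floor(v / binWidth + 0.5)
  k0 <- min(k)
  idx <- as.integer(k - k0) + 1L
  nb <- max(idx)
  new("IntensityHistogram",
      mids = (k0 + seq_len(nb) - 1) * binWidth,
      counts = as.numeric(tabulate(idx, nbins = nb)))
}
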