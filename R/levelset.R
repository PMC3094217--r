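## Slice-propagated liver segmentation.
##
## Each axial slice is segmented by a 2D level-set without advection: the
## parenchyma intensity law is re-estimated on every slice by fitting a
## Gaussian to the histogram inside the slice's initial solution, a
## piecewise-linear speed image is derived from the two Gaussian-factor
## thresholds, and the signed-distance field evolves under propagation and
## curvature forces until the RMS change over the interface cells falls
## below the convergence threshold. The segmentation then walks the volume
## both superiorly and inferiorly, seeding each slice with its neighbour's
## result, and stops in a direction when the contour vanishes.

# histogram of a numeric vector with bins centered on multiples of binWidth
histogramFromValues <- function(v, binWidth = 1) {
  k <- floor(v / binWidth + 0.5)
  k0 <- min(k)
  idx <- as.integer(k - k0) + 1L
  nb <- max(idx)
  new("IntensityHistogram",
      mids = (k0 + seq_len(nb) - 1) * binWidth,
      counts = as.numeric(tabulate(idx, nbins = nb)))
}

#' Speed image for the threshold-driven level set
#'
#' The propagation image is piecewise linear in the intensity `g`:
#' `P = g - T_L` below the threshold midpoint and `P = T_H - g` above it.
#' It is positive exactly where `T_L < g < T_H`, zero at the thresholds,
#' negative outside and maximal (`(T_H - T_L)/2`) at the midpoint, so the
#' contour expands over parenchyma-like intensities and shrinks elsewhere,
#' slowing to a halt at the learned boundaries. The curvature spatial
#' modifier `Z` is the positive part of `P` rescaled to `[0, 1]`, so the
#' smoothing force loses importance close to those same boundaries.
#'
#' @param slice 2D numeric matrix of intensities.
#' @param thresholds named numeric `c(low =, high =)` with `low < high`.
#' @return list with matrices `P` and `Z`.
#' @export
speedImage <- function(slice, thresholds) {
  tl <- thresholds[["low"]]; th <- thresholds[["high"]]
  if (!(tl < th)) stop("thresholds must satisfy low < high")
  mid <- (tl + th) / 2
  P <- ifelse(slice < mid, slice - tl, th - slice)
  pmax <- max(P)
  Z <- if (pmax > 0) pmax(P, 0) / pmax else array(0, dim(P))
  list(P = P, Z = Z)
}

# shift a matrix with replicated (Neumann) edges
shiftEdge2 <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  yi <- pmin(pmax(seq_len(ny) - dy, 1), ny)
  xi <- pmin(pmax(seq_len(nx) - dx, 1), nx)
  m[yi, xi]
}

# one explicit upwind/curvature update of phi; returns list(phi, rms)
levelSetStep <- function(phi, F, gz, band) {
  dmy <- phi - shiftEdge2(phi, 1, 0); dpy <- shiftEdge2(phi, -1, 0) - phi
  dmx <- phi - shiftEdge2(phi, 0, 1); dpx <- shiftEdge2(phi, 0, -1) - phi
  gradPlus <- sqrt(pmax(dmy, 0)^2 + pmin(dpy, 0)^2 +
                   pmax(dmx, 0)^2 + pmin(dpx, 0)^2)
  gradMinus <- sqrt(pmin(dmy, 0)^2 + pmax(dpy, 0)^2 +
                    pmin(dmx, 0)^2 + pmax(dpx, 0)^2)
  ## central differences for the curvature
  py <- (dpy + dmy) / 2; px <- (dpx + dmx) / 2
  pyy <- dpy - dmy; pxx <- dpx - dmx
  pxy <- (shiftEdge2(phi, -1, -1) + shiftEdge2(phi, 1, 1) -
          shiftEdge2(phi, -1, 1) - shiftEdge2(phi, 1, -1)) / 4
  g2 <- px^2 + py^2
  K <- (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) / (g2^1.5 + 1e-8)
  # curvature magnitudes beyond 1/h are grid artefacts
  K <- pmin(pmax(K, -1), 1)
  gradC <- sqrt(g2)
  dphi <- -(pmax(F, 0) * gradPlus + pmin(F, 0) * gradMinus) + gz * K * gradC
  dphi[!band] <- 0
  dphi
}

#' Segment one axial slice with the threshold level set
#'
#' Fits a Gaussian to the intensity histogram inside the initial mask,
#' derives the parenchyma thresholds from the low/high Gaussian factors,
#' builds the speed image, and evolves the signed-distance field (negative
#' inside) with upwind propagation and finite-difference curvature until
#' the RMS change over the interface cells drops below `minRMS` or the
#' iteration cap is reached. The field is periodically reinitialized to a
#' signed distance and updates are restricted to a narrow band around the
#' interface.
#'
#' @param slice 2D numeric matrix of intensities.
#' @param init 2D binary matrix, nonempty initial solution.
#' @param params a [levelSetParams()] bundle.
#' @param guardModel optional [GaussianModel-class] carrying the running
#'   parenchyma law of the exam. The per-slice refit is rejected — and the
#'   guard model used instead — when its mean departs from the guard's by
#'   more than 3 guard sigmas or its width changes more than threefold:
#'   such a fit means the initial solution has drifted onto a different
#'   structure, and keeping parenchymal thresholds is what lets the contour
#'   vanish beyond the organ limits.
#' @return 2D binary (0/1) matrix; may be empty if the contour vanished.
#'   Attributes carry the iteration count, thresholds and the accepted
#'   Gaussian model.
#' @export
evolveSlice <- function(slice, init, params, guardModel = NULL) {
  stopifnot(is(params, "LevelSetParams"))
  if (!is.matrix(slice)) stop("slice must be a 2D matrix")
  if (sum(init != 0) == 0) stop("initial solution is empty")
  g <- fitGaussian(histogramFromValues(slice[init != 0]))
  if (!is.null(guardModel)) {
    inconsistent <- abs(g@mu - guardModel@mu) > 3 * guardModel@sigma ||
      g@sigma > 3 * guardModel@sigma || g@sigma < guardModel@sigma / 3
    if (inconsistent) g <- guardModel
  }
  thr <- thresholdsFromGaussian(g, params@gLow, params@gHigh)
  sp <- speedImage(slice, thr)
  # only the sign and the near-threshold profile of P matter; clamping the
  # far-from-threshold magnitudes at the maximum positive speed keeps the
  # Courant step balanced between expansion and shrinkage
  pClip <- max(sp$P, 0)
  Pc <- if (max(pClip) > 0) pmin(pmax(sp$P, -max(pClip)), max(pClip)) else sp$P
  F <- params@beta * Pc
  gz <- params@gamma * sp$Z

  bandWidth <- 6; reinitEvery <- 10L
  # the distance transform is exact but kinked at the voxel scale; a light
  # blur keeps the curvature estimate smooth without moving the interface
  smoothSDF <- function(m) EBImage::gblur(signedDistance2D(m), sigma = 0.7)
  phi <- smoothSDF(init != 0)
  belowCount <- 0L
  prevMask <- init != 0
  for (iter in seq_len(params@maxIterations)) {
    if ((iter - 1L) %% reinitEvery == 0L && iter > 1L) {
      cur <- phi < 0
      if (!any(cur)) break
      # discrete stationarity: if no voxel changed membership over a full
      # reinitialization cycle the interface has converged, whatever the
      # sub-voxel jitter of the field
      if (identical(cur, prevMask)) break
      prevMask <- cur
      phi <- smoothSDF(cur)
    }
    band <- abs(phi) <= bandWidth
    dphi <- levelSetStep(phi, F, gz, band)
    maxUpdate <- max(abs(dphi))
    if (maxUpdate <= 0) break
    # Courant bound on the computed update, as dense explicit level-set
    # solvers do: the fastest cell moves at most 0.45 voxel per iteration
    dt <- 0.45 / maxUpdate
    active <- abs(phi) <= 1
    phi <- pmin(pmax(phi + dt * dphi, -(bandWidth + 2)), bandWidth + 2)
    if (!any(active)) break
    rms <- sqrt(mean((dt * dphi[active])^2))
    belowCount <- if (rms < params@minRMS) belowCount + 1L else 0L
    if (iter > 5L && belowCount >= 3L) break
  }
  out <- matrix(as.integer(phi < 0), nrow(slice), ncol(slice))
  attr(out, "iterations") <- iter
  attr(out, "thresholds") <- thr
  attr(out, "model") <- g
  out
}

#' Segment the liver through a whole CT volume
#'
#' Runs [evolveSlice()] on the starting slice, then propagates both
#' superiorly and inferiorly, seeding each slice with the adjacent slice's
#' result. A per-slice 2D fill-holes step merges vessels and nodules that
#' are completely enclosed by parenchyma into the liver. Propagation in a
#' direction ends at the volume boundary or as soon as a slice's contour
#' vanishes, which marks the anatomical limit of the liver.
#'
#' @param volume a [CTVolume-class].
#' @param initSliceIndex axial (z) index of the slice carrying the initial
#'   solution.
#' @param initMask2d 2D binary matrix (ny x nx), nonempty; a rough manual
#'   delineation that only needs to contain a representative chunk of liver.
#' @param params a [levelSetParams()] bundle.
#' @param fillHoles apply the per-slice hole-filling correction
#'   (default TRUE).
#' @return A [VoxelMask-class] on the volume's grid. The attribute
#'   `"sliceIterations"` records the level-set iteration count per visited
#'   slice.
#' @export
segmentLiver <- function(volume, initSliceIndex, initMask2d, params,
                         fillHoles = TRUE) {
  stopifnot(is(volume, "CTVolume"))
  d <- dim(volume@data)
  if (initSliceIndex < 1 || initSliceIndex > d[1])
    stop("initSliceIndex outside the volume")
  if (!all(dim(initMask2d) == d[2:3]))
    stop("initMask2d geometry does not match the volume's axial slices")
  if (sum(initMask2d != 0) == 0) stop("initial solution is empty")

  out <- array(0L, d)
  iterations <- setNames(integer(0), character(0))
  guard <- NULL
  runSlice <- function(z, seed) {
    res <- tryCatch(
      evolveSlice(volume@data[z, , ], seed, params, guardModel = guard),
      error = function(e) stop("slice ", z, ": ", conditionMessage(e),
                               call. = FALSE))
    iterations[as.character(z)] <<- attr(res, "iterations")
    guard <<- attr(res, "model")
    if (fillHoles && any(res != 0)) res <- fillHoles2D(res)
    res
  }

  start <- runSlice(initSliceIndex, initMask2d)
  startGuard <- guard
  out[initSliceIndex, , ] <- start
  for (dir in c(1L, -1L)) {
    seed <- start
    guard <- startGuard
    z <- initSliceIndex + dir
    while (z >= 1L && z <= d[1] && sum(seed) > 0) {
      seed <- runSlice(z, seed)
      out[z, , ] <- seed
      z <- z + dir
    }
  }
  mask <- voxelMask(out, like = volume)
  attr(mask, "sliceIterations") <- iterations
  mask
}
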