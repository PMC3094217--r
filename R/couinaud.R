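## Geometric Couinaud partition: one near-vertical least-squares plane per
## hepatic vein branch and one near-horizontal plane for the portal vein;
## the four planes bound the eight Couinaud regions. The purely geometric
## construction cannot isolate the caudate lobe (segment I, drained by the
## cava vein); the medial-posterior-superior slab only loosely approximates
## it, which is documented in the legend as "IVa (I proxy)".

#' Fit an oriented plane to 3D points by least squares
#'
#' Near-vertical planes solve `x = a*y + b*z + c`, near-horizontal planes
#' `z = a*x + b*y + c` (all coordinates in mm); the parameterization itself
#' enforces the orientation class. The normal equations are solved by QR.
#'
#' @param points numeric matrix with columns (z, y, x) in mm, at least 3
#'   non-collinear rows.
#' @param orientation `"near_vertical"` or `"near_horizontal"`.
#' @return A [PlaneModel-class].
#' @export
fitPlane <- function(points, orientation = c("near_vertical",
                                             "near_horizontal")) {
  orientation <- match.arg(orientation)
  if (nrow(points) < 3) stop("need at least 3 points to fit a plane")
  z <- points[, 1]; y <- points[, 2]; x <- points[, 3]
  X <- if (orientation == "near_vertical") cbind(y, z, 1) else cbind(x, y, 1)
  response <- if (orientation == "near_vertical") x else z
  qrX <- qr(X)
  if (qrX$rank < 3)
    stop("degenerate geometry: points do not determine a plane of this orientation")
  coefs <- qr.coef(qrX, response)
  new("PlaneModel", orientation = orientation,
      coefficients = as.numeric(coefs))
}

#' Signed residual of voxel coordinates against a plane
#'
#' Positive residuals are on the +x side of a near-vertical plane and the
#' +z (superior) side of a near-horizontal plane.
#'
#' @param plane a [PlaneModel-class].
#' @param coords matrix with columns (z, y, x) in mm.
#' @return numeric vector of signed distances along the response axis.
#' @export
planeResidual <- function(plane, coords) {
  cf <- plane@coefficients
  if (plane@orientation == "near_vertical")
    coords[, 3] - (cf[1] * coords[, 2] + cf[2] * coords[, 1] + cf[3])
  else
    coords[, 1] - (cf[1] * coords[, 3] + cf[2] * coords[, 2] + cf[3])
}

couinaudLegend <- c(
  "1" = "VII (right posterior superior)",
  "2" = "VI (right posterior inferior)",
  "3" = "VIII (right anterior superior)",
  "4" = "V (right anterior inferior)",
  "5" = "IVa (medial superior, I proxy)",
  "6" = "IVb (medial inferior)",
  "7" = "II (left superior)",
  "8" = "III (left inferior)")

#' Partition the liver into the eight Couinaud regions
#'
#' Each liver voxel gets a lateral slab index (how many of the three
#' near-vertical hepatic planes, ordered right to left, lie to its right)
#' and a superior/inferior flag from the portal plane; the 4 x 2 codes map
#' to the eight region labels. Voxels exactly on a plane are assigned to
#' the right/inferior side. Side tests use signed residuals of the plane
#' equations at the voxel centres in mm, so anisotropic spacing is handled
#' correctly.
#'
#' @param liver liver [VoxelMask-class].
#' @param hepaticPlanes list of 3 near-vertical [PlaneModel-class]; they are
#'   ordered right-to-left by their mean x over the liver internally.
#' @param portalPlane one near-horizontal [PlaneModel-class].
#' @return A [LabelVolume-class] with labels 1..8 inside the liver and the
#'   Couinaud legend. A warning is emitted (and attribute `emptyLabels`
#'   set) when a plane misses the liver and some regions are empty.
#' @export
partitionCouinaud <- function(liver, hepaticPlanes, portalPlane) {
  stopifnot(length(hepaticPlanes) == 3,
    all(vapply(hepaticPlanes, function(p) p@orientation, "") ==
          "near_vertical"),
    portalPlane@orientation == "near_horizontal")
  d <- dim(voxelData(liver))
  idx <- which(voxelData(liver) != 0)
  if (!length(idx)) stop("empty liver mask")
  coords <- voxelCoordsMm(liver, idx)
  ## order planes right -> left: patient right is negative x, so ascending
  ## mean plane-x over the liver footprint
  planeX <- vapply(hepaticPlanes, function(p) {
    cf <- p@coefficients
    mean(cf[1] * coords[, 2] + cf[2] * coords[, 1] + cf[3])
  }, 0)
  hepaticPlanes <- hepaticPlanes[order(planeX)]
  slab <- rep(0L, length(idx))
  for (p in hepaticPlanes) slab <- slab + (planeResidual(p, coords) > 0)
  superior <- planeResidual(portalPlane, coords) > 0
  ## slab 0 = right posterior ... slab 3 = left; codes -> labels
  labelOf <- matrix(1:8, nrow = 2)    # [sup/inf, slab+1]
  lab <- labelOf[cbind(ifelse(superior, 1L, 2L), slab + 1L)]
  arr <- array(0L, d)
  arr[idx] <- lab
  empty <- setdiff(1:8, unique(lab))
  out <- labelVolume(arr, legend = couinaudLegend, like = liver)
  if (length(empty)) {
    warning("Couinaud regions with no voxels: ",
            paste(couinaudLegend[as.character(empty)], collapse = ", "))
    attr(out, "emptyLabels") <- empty
  }
  out
}

#' Couinaud partition from identified veins
#'
#' Fits one near-vertical plane to each hepatic branch and a near-horizontal
#' plane to the portal vein, then partitions the liver.
#'
#' @param liver liver [VoxelMask-class].
#' @param veins result of [identifyVeins()].
#' @return list with the [LabelVolume-class] `labels`, the fitted `planes`
#'   and per-segment volumes in ml (`volumesMl`).
#' @export
couinaudFromVeins <- function(liver, veins) {
  if (length(veins$branches) < 3)
    stop("need 3 hepatic branches to build the Couinaud partition")
  hp <- lapply(veins$branches, function(b)
    fitPlane(voxelCoordsMm(b), "near_vertical"))
  if (maskVoxelCount(veins$portal) < 3)
    stop("portal vein too small to fit a plane")
  pp <- fitPlane(voxelCoordsMm(veins$portal), "near_horizontal")
  labels <- partitionCouinaud(liver, hp, pp)
  counts <- tabulate(voxelData(labels)[voxelData(labels) > 0], nbins = 8)
  vols <- counts * prod(voxelSpacing(liver)) / 1000
  list(labels = labels, planes = c(hp, list(portal = pp)),
       volumesMl = setNames(vols, couinaudLegend))
}
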