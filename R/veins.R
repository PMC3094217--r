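## Identification of the hepatic vein main branches and the portal vein.
##
## Three main branches are assumed for the hepatic veins (the arrangement
## found in about 80% of people), running predominantly vertically from the
## upper part of the liver downwards. Branches are tracked slice by slice by
## maximal footprint overlap, accepted when they span more than a fraction
## (default 15%) of the liver height, labelled right/middle/left by a clock
## rule on their coronal projections, and the portal vein is the largest
## connected component of what remains.

#' Track the main hepatic vein branches
#'
#' Starting from the most superior slice still containing unassigned vessel
#' voxels, the biggest in-slice connected component seeds a candidate that
#' is extended inferiorly by merging, slice by slice, the component with the
#' biggest footprint overlap, until no overlap remains. Candidates spanning
#' more than `minHeightFraction` of the liver height (both in mm) are
#' accepted; every processed candidate — accepted or not — is removed from
#' further seeding, which guarantees termination.
#'
#' @param vessels segmented vessel [VoxelMask-class].
#' @param liver liver [VoxelMask-class] (defines the liver height).
#' @param minHeightFraction acceptance rule on candidate height (default
#'   0.15).
#' @param nBranches number of branches sought (default 3).
#' @return list of up to `nBranches` [VoxelMask-class] branch masks, most
#'   superior seed first; attribute `flag = "fewer branches than expected"`
#'   when the seeds are exhausted early.
#' @export
trackMainBranches <- function(vessels, liver, minHeightFraction = 0.15,
                              nBranches = 3L) {
  stopIfGeometryDiffers(vessels, liver)
  v <- voxelData(vessels) != 0
  if (!any(v)) stop("empty vessel mask")
  d <- dim(v)
  sz <- voxelSpacing(vessels)[1]
  zs <- apply(voxelData(liver) != 0, 1, any)
  liverHeight <- sum(zs) * sz
  remaining <- v
  branches <- list()
  while (length(branches) < nBranches && any(remaining)) {
    hasV <- apply(remaining, 1, any)
    zTop <- max(which(hasV))          # most superior slice with vessels
    seedComp <- largestComponent2D(remaining[zTop, , ]) != 0
    cand <- array(FALSE, d)
    cand[zTop, , ] <- seedComp
    foot <- seedComp
    zLow <- zTop
    z <- zTop - 1L                    # posterior slice = next inferior
    while (z >= 1L) {
      lab <- EBImage::bwlabel(matrix(as.integer(remaining[z, , ]),
                                     d[2], d[3]))
      n <- max(lab)
      if (n == 0) break
      overlaps <- vapply(seq_len(n), function(k) sum(lab == k & foot), 0)
      if (max(overlaps) == 0) break
      # ties: larger component first, then smaller centroid x (column)
      sizes <- tabulate(lab[lab > 0], nbins = n)
      cx <- vapply(seq_len(n), function(k) mean(col(lab)[lab == k]), 0)
      best <- order(-overlaps, -sizes, cx)[1]
      sel <- lab == best
      cand[z, , ] <- cand[z, , ] | sel
      foot <- sel
      zLow <- z
      z <- z - 1L
    }
    height <- (zTop - zLow + 1L) * sz
    if (height > minHeightFraction * liverHeight)
      branches[[length(branches) + 1L]] <- voxelMask(
        array(as.integer(cand), d), like = vessels)
    remaining <- remaining & !cand
  }
  if (length(branches) < nBranches)
    attr(branches, "flag") <- "fewer branches than expected"
  branches
}

#' Label hepatic branches right/middle/left by the clock rule
#'
#' Branch centroids are projected on the coronal plane (x horizontal, z
#' vertical) and ordered by the clockwise angle around the thorax axis as
#' seen from anterior, 12 o'clock pointing superior: the first branch
#' clockwise is the right one, then the middle (central), then the left.
#' The clock centre defaults to the liver centroid (a proxy for the central
#' axis of the thorax); under the radiological convention the patient's
#' right lies at negative x displacement from that centre.
#'
#' @param branches list of branch [VoxelMask-class] (1 to 3).
#' @param center optional numeric(2) clock centre (x, z) in mm; defaults to
#'   the liver centroid when `liver` is given, else the branch centroid
#'   mean.
#' @param liver optional liver [VoxelMask-class] used for the default
#'   centre.
#' @return character vector of labels (`"right"`, `"middle"`, `"left"`)
#'   parallel to `branches`; attribute `missing` names the labels not
#'   assigned when fewer than 3 branches are present.
#' @export
classifyClockwise <- function(branches, center = NULL, liver = NULL) {
  if (length(branches) < 1 || length(branches) > 3)
    stop("expected 1 to 3 branches")
  cents <- t(vapply(branches, function(b) {
    xyz <- voxelCoordsMm(b)
    c(x = mean(xyz[, 3]), z = mean(xyz[, 1]))
  }, c(x = 0, z = 0)))
  if (anyDuplicated(round(cents, 9)))
    stop("tie: identical branch centroids cannot be ordered")
  if (is.null(center)) {
    center <- if (!is.null(liver)) {
      xyz <- voxelCoordsMm(liver)
      c(mean(xyz[, 3]), mean(xyz[, 1]))
    } else c(mean(cents[, 1]), min(cents[, 2]) - 1)
  }
  # clockwise angle from 12 o'clock, anterior view, patient right at
  # negative x: atan2(dx, dz) increases right -> middle -> left
  ang <- atan2(cents[, 1] - center[1], cents[, 2] - center[2])
  labels <- head(c("right", "middle", "left"),
                 length(branches))[order(order(ang))]
  if (length(branches) < 3)
    attr(labels, "missing") <- setdiff(c("right", "middle", "left"), labels)
  labels
}

#' Extract the portal vein and assign residual vessels
#'
#' After removing the hepatic branches, the portal vein is the biggest
#' connected component among the remaining vessels. Every other residual
#' component is merged into a hepatic branch it touches (26-connectivity,
#' largest contact first) or classified as auxiliary. The output conserves
#' the input vessel voxels exactly: branches + portal + auxiliary = vessels.
#'
#' @param vessels segmented vessel [VoxelMask-class].
#' @param branches list of hepatic branch [VoxelMask-class].
#' @return list with `portal` ([VoxelMask-class], possibly empty and
#'   flagged), `auxiliary` ([VoxelMask-class]) and `branches` (the input
#'   branches with touching residuals merged in).
#' @export
extractPortal <- function(vessels, branches) {
  v <- voxelData(vessels) != 0
  d <- dim(v)
  branchArr <- lapply(branches, function(b) voxelData(b) != 0)
  inBranch <- Reduce(`|`, branchArr, array(FALSE, d))
  residual <- v & !inBranch
  aux <- array(FALSE, d)
  portal <- array(FALSE, d)
  if (!any(residual)) {
    out <- voxelMask(array(0L, d), like = vessels)
    attr(out, "flag") <- "no vessels left after branch extraction"
    return(list(portal = out,
                auxiliary = voxelMask(array(as.integer(aux), d),
                                      like = vessels),
                branches = branches))
  }
  lab <- labelComponents3D(residual, 26L)
  portal <- lab == 1L                   # labels are size-ordered
  padBranch <- lapply(branchArr, function(b) padZero3(b))
  offs <- linearOffsets(dim(padBranch[[1]]), 26L)
  for (k in seq_len(max(lab))[-1]) {
    comp <- lab == k
    idx <- which(padZero3(comp) != 0)
    nb <- unique(as.vector(outer(idx, offs, "+")))
    contact <- vapply(padBranch, function(b) sum(b[nb]), 0)
    if (max(contact) > 0) {
      j <- which.max(contact)
      branchArr[[j]] <- branchArr[[j]] | comp
    } else {
      aux <- aux | comp
    }
  }
  list(
    portal = voxelMask(array(as.integer(portal), d), like = vessels),
    auxiliary = voxelMask(array(as.integer(aux), d), like = vessels),
    branches = lapply(branchArr, function(b)
      voxelMask(array(as.integer(b), d), like = vessels)))
}

#' Full vein identification
#'
#' Runs branch tracking, clock labelling and portal extraction, returning a
#' consolidated result.
#'
#' @inheritParams trackMainBranches
#' @return list with `branches` (named list right/middle/left of
#'   [VoxelMask-class], merged residuals included), `portal`, `auxiliary`,
#'   `labels` (labels in tracking order), `heights` (per-branch height in mm)
#'   and `labelVolume` (a [LabelVolume-class]: 1 right, 2 middle, 3 left,
#'   4 portal, 5 auxiliary).
#' @export
identifyVeins <- function(vessels, liver, minHeightFraction = 0.15,
                          nBranches = 3L) {
  tracked <- trackMainBranches(vessels, liver, minHeightFraction, nBranches)
  if (!length(tracked)) stop("no hepatic branch candidates accepted")
  labels <- classifyClockwise(tracked, liver = liver)
  pe <- extractPortal(vessels, tracked)
  branches <- setNames(pe$branches, labels)
  sz <- voxelSpacing(vessels)[1]
  heights <- vapply(pe$branches, function(b) {
    zs <- which(apply(voxelData(b) != 0, 1, any))
    (max(zs) - min(zs) + 1L) * sz
  }, 0)
  d <- dim(voxelData(vessels))
  lv <- array(0L, d)
  codes <- c(right = 1L, middle = 2L, left = 3L)
  for (nm in names(branches)) lv[voxelData(branches[[nm]]) != 0] <- codes[[nm]]
  lv[voxelData(pe$portal) != 0] <- 4L
  lv[voxelData(pe$auxiliary) != 0] <- 5L
  list(branches = branches, portal = pe$portal, auxiliary = pe$auxiliary,
       labels = labels, heights = setNames(heights, labels),
       labelVolume = labelVolume(lv,
         legend = c("1" = "right hepatic", "2" = "middle hepatic",
                    "3" = "left hepatic", "4" = "portal", "5" = "auxiliary"),
         like = vessels))
}
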