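## Dual-threshold region growing for adipose nodules and vessels inside the
## segmented liver, driven by the three-component intensity mixture.

#' Region-growing configuration
#'
#' @param proportion density-share level for the seed thresholds, in
#'   (0.5, 1); default 0.70.
#' @param connectivity 3D neighbourhood, 6 or 26 (default 26: thin oblique
#'   vessels fragment under 6-connectivity).
#' @return list of class `"growConfig"`.
#' @export
growConfig <- function(proportion = 0.70, connectivity = 26L) {
  if (proportion <= 0.5 || proportion >= 1)
    stop("proportion must lie in (0.5, 1)")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  structure(list(proportion = proportion,
                 connectivity = as.integer(connectivity)),
            class = "growConfig")
}

#' Seeded region growing under an acceptance rule
#'
#' Returns the set of domain voxels reachable from the seed voxels through
#' acceptance-rule voxels under the chosen connectivity — the fixed point of
#' iterated dilation masked by the acceptance set.
#'
#' @param volume a [CTVolume-class].
#' @param domain a [VoxelMask-class] restricting both seeds and growth.
#' @param seedRule,acceptRule one-argument functions mapping an intensity
#'   array to a logical array; the seed rule must be at least as strict as
#'   the acceptance rule.
#' @param connectivity 6 or 26.
#' @return A [VoxelMask-class]; empty (with attribute `flag =
#'   "no seeds"`) when the seed rule selects nothing.
#' @export
growRegion <- function(volume, domain, seedRule, acceptRule,
                       connectivity = 26L) {
  stopIfGeometryDiffers(volume, domain)
  g <- voxelData(volume)
  dom <- voxelData(domain) != 0
  if (!any(dom)) stop("empty domain")
  seeds <- which(seedRule(g) & dom)
  accept <- acceptRule(g) & dom
  if (!length(seeds)) {
    out <- voxelMask(array(0L, dim(g)), like = volume)
    attr(out, "flag") <- "no seeds"
    return(out)
  }
  grown <- floodFrom3D(accept, seeds, connectivity)
  voxelMask(grown, like = volume)
}

#' Segment adipose nodules inside the liver
#'
#' Voxels with intensity below the nodule seed threshold (the largest
#' intensity where the nodule component holds at least the configured share
#' of the nodule+parenchyma density) are taken as seeds; growth aggregates
#' neighbouring voxels with intensity below the nodule/parenchyma
#' intersection. Only nodules darker than the parenchyma (adipose) are in
#' scope.
#'
#' @param volume a [CTVolume-class].
#' @param liver the segmented liver [VoxelMask-class].
#' @param m a [MixtureModel-class] from [decomposeMixture()].
#' @param cfg a [growConfig()].
#' @return A [VoxelMask-class], empty with attribute
#'   `flag = "no adipose nodules"` when the left component is absent.
#' @export
segmentNodules <- function(volume, liver, m, cfg = growConfig()) {
  stopifnot(is(m, "MixtureModel"))
  if (!componentPresent(m, "left")) {
    out <- voxelMask(array(0L, dim(volume)), like = volume)
    attr(out, "flag") <- "no adipose nodules"
    return(out)
  }
  thr <- growThresholds(m, "left", cfg$proportion)
  growRegion(volume, liver,
             seedRule = function(g) g < thr[["low"]],
             acceptRule = function(g) g < thr[["high"]],
             connectivity = cfg$connectivity)
}

#' Segment vessels inside the liver
#'
#' Mirror of [segmentNodules()] on the bright side: voxels above the vessel
#' seed threshold are classified as vessels outright and grown through
#' voxels above the vessel/parenchyma intersection.
#'
#' @inheritParams segmentNodules
#' @return A [VoxelMask-class], empty with attribute
#'   `flag = "no vessels"` when the right component is absent.
#' @export
segmentVessels <- function(volume, liver, m, cfg = growConfig()) {
  stopifnot(is(m, "MixtureModel"))
  if (!componentPresent(m, "right")) {
    out <- voxelMask(array(0L, dim(volume)), like = volume)
    attr(out, "flag") <- "no vessels"
    return(out)
  }
  thr <- growThresholds(m, "right", cfg$proportion)
  growRegion(volume, liver,
             seedRule = function(g) g > thr[["high"]],
             acceptRule = function(g) g > thr[["low"]],
             connectivity = cfg$connectivity)
}
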