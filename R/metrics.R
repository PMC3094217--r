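## Segmentation disparity metrics and human-error-anchored scoring.
##
## Five metrics compare a segmentation to a reference: volumetric overlap
## error (VOE, %), signed relative volume difference (RVD, %), and three
## symmetric border-distance statistics in mm (average ASD, root mean
## square RMSSD, maximum MSD). Each maps to a score in [0, 100] anchored on
## the mean human (inter-observer) error: a perfect match scores 100, an
## error equal to the human reference scores 75, decreasing linearly and
## clamped at 0. The total score — the mean of the five — is the quantity
## the genetic parameter search maximizes.

#' Human inter-observer error references
#'
#' One strictly positive value per metric, in that metric's units. These
#' are configuration: they depend on the reference corpus and are never
#' defaulted.
#'
#' @param voe,rvd,asd,rmssd,msd positive scalars.
#' @return named numeric vector of class `"humanErrorRefs"`.
#' @export
humanErrorRefs <- function(voe, rvd, asd, rmssd, msd) {
  v <- c(voe = voe, rvd = rvd, asd = asd, rmssd = rmssd, msd = msd)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("human error references must all be strictly positive")
  structure(v, class = "humanErrorRefs")
}

# minimum distance from each row of `a` to the point set `b` (both n x 3,
# mm), chunked to bound memory. The quadratic expansion locates candidate
# nearest neighbours quickly; the distance itself is then recomputed by the
# direct difference, which is accurate to machine precision.
minDistToSet <- function(a, b, chunk = 512L) {
  out <- numeric(nrow(a))
  b2 <- rowSums(b^2)
  for (i in seq(1, nrow(a), by = chunk)) {
    j <- i:min(i + chunk - 1L, nrow(a))
    aj <- a[j, , drop = FALSE]
    d2 <- outer(rowSums(aj^2), b2, "+") - 2 * (aj %*% t(b))
    m <- apply(d2, 1, min)
    # all near-ties are re-evaluated exactly
    cand <- which(d2 <= m + 1e-6, arr.ind = TRUE)
    exact <- sqrt(rowSums((aj[cand[, 1], , drop = FALSE] -
                           b[cand[, 2], , drop = FALSE])^2))
    out[j] <- vapply(seq_along(j), function(r)
      min(exact[cand[, 1] == r]), 0)
  }
  out
}

#' Compute the five disparity metrics
#'
#' VOE and RVD are voxel-count based; the distance metrics are Euclidean
#' distances in mm between border-voxel centres (a border voxel is a mask
#' voxel with a 6-neighbour outside, the volume edge counting as outside),
#' symmetrized over both border sets.
#'
#' @param seg segmentation [VoxelMask-class].
#' @param ref reference [VoxelMask-class], nonempty, same geometry.
#' @return named numeric `c(voe =, rvd =, asd =, rmssd =, msd =)`; VOE and
#'   RVD in percent (RVD signed), distances in mm.
#' @export
computeMetrics <- function(seg, ref) {
  stopIfGeometryDiffers(seg, ref)
  s <- voxelData(seg) != 0
  r <- voxelData(ref) != 0
  if (!any(r)) stop("empty reference mask")
  nInter <- sum(s & r); nUnion <- sum(s | r)
  voe <- 100 * (1 - nInter / nUnion)
  rvd <- 100 * (sum(s) - sum(r)) / sum(r)
  if (!any(s))
    stop("empty segmentation: surface distances are undefined ",
         "(voe = 100, rvd = -100)")
  bs <- borderVoxels3D(s); br <- borderVoxels3D(r)
  ms <- voxelMask(array(as.integer(bs), dim(bs)), like = seg)
  cs <- voxelCoordsMm(ms)
  mr <- voxelMask(array(as.integer(br), dim(br)), like = ref)
  cr <- voxelCoordsMm(mr)
  dists <- c(minDistToSet(cs, cr), minDistToSet(cr, cs))
  c(voe = voe, rvd = rvd, asd = mean(dists),
    rmssd = sqrt(mean(dists^2)), msd = max(dists))
}

#' Score one metric against its human error reference
#'
#' `score = max(0, 100 - 25 * |error| / humanError)`: 100 for a perfect
#' match, 75 when the error equals the mean human error, linear in between
#' and beyond, clamped at zero.
#'
#' @param errorValue the metric value (sign ignored).
#' @param humanError strictly positive reference for this metric.
#' @return score in [0, 100].
#' @export
scoreMetric <- function(errorValue, humanError) {
  if (!is.finite(humanError) || humanError <= 0)
    stop("humanError must be strictly positive")
  pmax(0, 100 - 25 * abs(errorValue) / humanError)
}

#' Score a metric set and build a report
#'
#' @param metrics named numeric as returned by [computeMetrics()].
#' @param refs a [humanErrorRefs()].
#' @return A [MetricReport-class] with per-metric scores and their mean as
#'   the total score.
#' @export
totalScore <- function(metrics, refs) {
  stopifnot(inherits(refs, "humanErrorRefs"))
  metrics <- metrics[metricNames]
  scores <- vapply(metricNames, function(m)
    scoreMetric(metrics[[m]], refs[[m]]), 0)
  new("MetricReport", metrics = setNames(as.numeric(metrics), metricNames),
      scores = setNames(scores, metricNames),
      totalScore = mean(scores))
}

#' Evaluate a segmentation against a reference
#'
#' Convenience wrapper: [computeMetrics()] then [totalScore()].
#'
#' @inheritParams computeMetrics
#' @param refs a [humanErrorRefs()].
#' @return A [MetricReport-class].
#' @export
evaluateSegmentation <- function(seg, ref, refs) {
  totalScore(computeMetrics(seg, ref), refs)
}
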