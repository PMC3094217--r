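#' @import methods
#' @importFrom stats coef rnorm runif setNames
#' @importFrom utils head
#' @importFrom EBImage gblur distmap fillHull bwlabel
#' @importFrom minpack.lm nlsLM nls.lm nls.lm.control
#' @importFrom jsonlite write_json
#' @importFrom RNifti readNifti writeNifti asNifti pixdim
NULL

## Voxel grids ---------------------------------------------------------------

#' CTVolume: a 3D scalar voxel grid with anisotropic spacing
#'
#' The central carrier for CT exams and derived scalar fields. The array is
#' indexed `[z, y, x]` (axial slice, row, column), with z increasing from
#' inferior to superior, and `spacing`/`origin` stored in the same (z, y, x)
#' order, in millimetres. Intensities are kept verbatim — no rescaling or
#' windowing is ever applied on I/O, because all thresholds used downstream
#' are learned from the data itself.
#'
#' @slot data 3D numeric/integer array indexed `[z, y, x]`.
#' @slot spacing numeric(3), voxel spacing (sz, sy, sx) in mm, all > 0.
#' @slot origin numeric(3), position (oz, oy, ox) of voxel `[1,1,1]` in mm.
#' @export
setClass("CTVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(data = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array indexed [z, y, x]")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values (mm)")
  if (length(msg)) msg else TRUE
})

#' VoxelMask: a binary voxel grid aligned to a CTVolume
#'
#' Values are restricted to {0, 1}; geometry (shape, spacing, origin) must
#' match the companion volume. Used for the liver, vessel, nodule and portal
#' segmentation outputs.
#'
#' @export
setClass("VoxelMask", contains = "CTVolume")

setValidity("VoxelMask", function(object) {
  v <- as.vector(object@data)
  if (!all(v == 0 | v == 1))
    "mask values must be exactly 0 or 1" else TRUE
})

#' LabelVolume: a small-integer label grid with a legend
#'
#' Carrier for the hepatic branch labels and the Couinaud partition. Every
#' nonzero label present in the data must be named in `legend` (a character
#' vector whose names are the label integers).
#'
#' @slot legend named character vector mapping label -> region name.
#' @export
setClass("LabelVolume", contains = "CTVolume",
  representation(legend = "character"))

setValidity("LabelVolume", function(object) {
  v <- as.vector(object@data)
  if (any(v < 0) || any(v != round(v)))
    return("labels must be non-negative integers")
  lab <- sort(unique(v[v > 0]))
  have <- suppressWarnings(as.numeric(names(object@legend)))
  if (length(lab) && !all(lab %in% have))
    return("every nonzero label must appear in the legend")
  TRUE
})

## Intensity models ----------------------------------------------------------

#' IntensityHistogram: equally spaced intensity histogram
#'
#' @slot mids strictly increasing, uniformly spaced bin centers.
#' @slot counts non-negative counts, one per bin.
#' @export
setClass("IntensityHistogram",
  representation(mids = "numeric", counts = "numeric"))

setValidity("IntensityHistogram", function(object) {
  msg <- character()
  if (length(object@mids) != length(object@counts))
    msg <- c(msg, "mids and counts must have equal length")
  if (length(object@mids) > 1) {
    d <- diff(object@mids)
    if (any(d <= 0)) msg <- c(msg, "bin centers must be strictly increasing")
    if (max(d) - min(d) > 1e-8 * max(abs(d)))
      msg <- c(msg, "bin centers must be uniformly spaced")
  }
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' GaussianModel: amplitude-mean-width Gaussian K * exp(-(x-mu)^2 / (2 sigma^2))
#'
#' `flag` records fit provenance: "ok", "absent" (component judged not
#' present in a mixture) or "degenerate" (sigma floored on a collapsed
#' histogram).
#'
#' @export
setClass("GaussianModel",
  representation(K = "numeric", mu = "numeric", sigma = "numeric",
                 flag = "character"),
  prototype(K = 0, mu = 0, sigma = 1, flag = "ok"))

setValidity("GaussianModel", function(object) {
  msg <- character()
  if (length(object@K) != 1 || object@K < 0) msg <- c(msg, "K must be >= 0")
  if (length(object@sigma) != 1 || object@sigma <= 0)
    msg <- c(msg, "sigma must be > 0")
  if (!object@flag %in% c("ok", "absent", "degenerate"))
    msg <- c(msg, "flag must be ok/absent/degenerate")
  if (length(msg)) msg else TRUE
})

#' MixtureModel: three-component intra-liver intensity mixture
#'
#' Components ordered by mean: `left` (adipose nodules, darkest), `centre`
#' (parenchyma, dominant), `right` (vessels, brightest). Side components may
#' carry flag "absent" when no such tissue class is supported by the
#' histogram.
#'
#' @export
setClass("MixtureModel",
  representation(left = "GaussianModel", centre = "GaussianModel",
                 right = "GaussianModel"))

setValidity("MixtureModel", function(object) {
  l <- object@left; c0 <- object@centre; r <- object@right
  ok <- (l@flag == "absent" || l@mu < c0@mu) &&
        (r@flag == "absent" || r@mu > c0@mu)
  if (!ok) "component means must satisfy mu_left < mu_centre < mu_right"
  else TRUE
})

## Parameter bundles ----------------------------------------------------------

#' LevelSetParams: the five tunable liver level-set parameters
#'
#' @slot minRMS convergence criterion on the RMS change of the level-set
#'   field over the interface cells (> 0).
#' @slot gLow,gHigh Gaussian low/high factors in (0,1) defining the
#'   parenchyma thresholds from the per-slice Gaussian fit.
#' @slot beta propagation weight. Under this package's sign convention a
#'   positive beta expands the contour where the intensity lies inside
#'   [T_L, T_H].
#' @slot gamma mean-curvature weight (>= 0).
#' @slot maxIterations per-slice safety cap on iterations.
#' @export
setClass("LevelSetParams",
  representation(minRMS = "numeric", gLow = "numeric", gHigh = "numeric",
                 beta = "numeric", gamma = "numeric",
                 maxIterations = "integer"))

setValidity("LevelSetParams", function(object) {
  msg <- character()
  if (object@minRMS <= 0) msg <- c(msg, "minRMS must be > 0")
  if (object@gLow <= 0 || object@gLow >= 1) msg <- c(msg, "gLow must be in (0,1)")
  if (object@gHigh <= 0 || object@gHigh >= 1) msg <- c(msg, "gHigh must be in (0,1)")
  if (object@gamma < 0) msg <- c(msg, "gamma must be >= 0")
  if (object@maxIterations < 1L) msg <- c(msg, "maxIterations must be >= 1")
  if (length(msg)) msg else TRUE
})

#' MetricReport: the five disparity metrics, their scores and the total
#'
#' @slot metrics named numeric: voe (%), rvd (signed %), asd, rmssd, msd (mm).
#' @slot scores named numeric in [0, 100], same names.
#' @slot totalScore arithmetic mean of the five scores.
#' @export
setClass("MetricReport",
  representation(metrics = "numeric", scores = "numeric",
                 totalScore = "numeric"))

metricNames <- c("voe", "rvd", "asd", "rmssd", "msd")

setValidity("MetricReport", function(object) {
  msg <- character()
  if (!identical(names(object@metrics), metricNames))
    msg <- c(msg, "metrics must be named voe, rvd, asd, rmssd, msd")
  if (!identical(names(object@scores), metricNames))
    msg <- c(msg, "scores must be named voe, rvd, asd, rmssd, msd")
  if (any(object@scores < 0 | object@scores > 100))
    msg <- c(msg, "scores must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' PlaneModel: an oriented least-squares plane in mm coordinates
#'
#' Near-vertical planes are parameterized as x = a*y + b*z + c (they separate
#' left from right); near-horizontal planes as z = a*x + b*y + c (they
#' separate superior from inferior). The parameterization itself enforces the
#' orientation class.
#'
#' @export
setClass("PlaneModel",
  representation(orientation = "character", coefficients = "numeric"))

setValidity("PlaneModel", function(object) {
  msg <- character()
  if (!object@orientation %in% c("near_vertical", "near_horizontal"))
    msg <- c(msg, "orientation must be near_vertical or near_horizontal")
  if (length(object@coefficients) != 3 || any(!is.finite(object@coefficients)))
    msg <- c(msg, "coefficients must be 3 finite values (a, b, c)")
  if (length(msg)) msg else TRUE
})
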