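## End-to-end orchestration of the four stages: liver -> nodules/vessels ->
## vein identification -> Couinaud partition, with a consolidated report.

#' Run the surgical-planning segmentation pipeline
#'
#' Executes, in order, the stages requested: `"liver"` (slice-propagated
#' level set), `"structures"` (mixture decomposition + region growing for
#' nodules and vessels), `"veins"` (hepatic branch tracking, clock
#' labelling, portal extraction) and `"couinaud"` (plane fitting and
#' region labelling). Later stages use the earlier stages' outputs; any of
#' them can instead be supplied precomputed, so partial reruns are
#' possible. A stage failure aborts the remaining stages with an error
#' naming the stage.
#'
#' @param volume a [CTVolume-class].
#' @param initSliceIndex,initMask2d initial solution for the liver stage
#'   (required when `"liver"` is among `stages`).
#' @param params a [levelSetParams()].
#' @param stages character subset of
#'   `c("liver", "structures", "veins", "couinaud")`.
#' @param liver,vessels,nodules optional precomputed [VoxelMask-class]
#'   inputs for runs that skip earlier stages.
#' @param cfg a [growConfig()] for the structures stage.
#' @param reference optional reference liver [VoxelMask-class]; when given
#'   together with `humanErrors`, the report includes the five disparity
#'   metrics and scores.
#' @param humanErrors optional [humanErrorRefs()].
#' @param outDir optional directory; when given, every produced mask is
#'   written there as MetaImage together with `report.json`.
#' @param verbose log stage progress to stderr.
#' @return list with the produced objects (`liver`, `mixture`, `nodules`,
#'   `vessels`, `veins`, `couinaud`, `evaluation`) and `report`, a
#'   JSON-ready list recording every numeric parameter used (level-set
#'   parameters, mixture parameters, growing thresholds, branch labels and
#'   heights, plane coefficients, per-segment volumes, per-slice level-set
#'   iteration counts).
#' @export
runPipeline <- function(volume, initSliceIndex = NULL, initMask2d = NULL,
                        params = levelSetParams(),
                        stages = c("liver", "structures", "veins",
                                   "couinaud"),
                        liver = NULL, vessels = NULL, nodules = NULL,
                        cfg = growConfig(), reference = NULL,
                        humanErrors = NULL, outDir = NULL, verbose = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  say <- function(...) if (verbose) message("[hepatoseg] ", ...)
  inStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  report <- list(
    package = "hepatoseg",
    reportVersion = 1L,
    parameters = list(minRMS = params@minRMS, gLow = params@gLow,
                      gHigh = params@gHigh, beta = params@beta,
                      gamma = params@gamma,
                      maxIterations = params@maxIterations,
                      growProportion = cfg$proportion,
                      growConnectivity = cfg$connectivity))
  out <- list()

  if ("liver" %in% stages) {
    if (is.null(initSliceIndex) || is.null(initMask2d))
      stop("stage 'liver' requires initSliceIndex and initMask2d")
    say("liver level-set segmentation")
    liver <- inStage("liver",
      segmentLiver(volume, initSliceIndex, initMask2d, params))
    report$liver <- list(
      voxels = maskVoxelCount(liver),
      volumeMl = maskVolumeMl(liver),
      sliceIterations = as.list(attr(liver, "sliceIterations")))
  }
  out$liver <- liver

  if ("structures" %in% stages) {
    if (is.null(liver)) stop("stage 'structures' requires a liver mask")
    say("mixture decomposition and region growing")
    res <- inStage("structures", {
      mix <- decomposeMixture(intensityHistogram(volume, liver))
      nod <- segmentNodules(volume, liver, mix, cfg)
      ves <- segmentVessels(volume, liver, mix, cfg)
      list(mix = mix, nod = nod, ves = ves)
    })
    out$mixture <- res$mix
    nodules <- res$nod; vessels <- res$ves
    gtr <- function(side) {
      ok <- componentPresent(res$mix, side) &&
        componentPresent(res$mix, "centre")
      if (!ok) return(NULL)
      as.list(growThresholds(res$mix, side, cfg$proportion))
    }
    mixPar <- function(g) list(K = g@K, mu = g@mu, sigma = g@sigma,
                               flag = g@flag)
    report$mixture <- list(
      left = mixPar(res$mix@left), centre = mixPar(res$mix@centre),
      right = mixPar(res$mix@right),
      noduleThresholds = gtr("left"), vesselThresholds = gtr("right"))
    report$structures <- list(noduleVoxels = maskVoxelCount(nodules),
                              vesselVoxels = maskVoxelCount(vessels))
  }
  out$nodules <- nodules
  out$vessels <- vessels

  if ("veins" %in% stages) {
    if (is.null(vessels)) stop("stage 'veins' requires a vessel mask")
    if (is.null(liver)) stop("stage 'veins' requires a liver mask")
    say("hepatic/portal vein identification")
    veins <- inStage("veins", identifyVeins(vessels, liver))
    out$veins <- veins
    report$veins <- list(
      labels = veins$labels,
      heightsMm = as.list(veins$heights),
      portalVoxels = maskVoxelCount(veins$portal),
      auxiliaryVoxels = maskVoxelCount(veins$auxiliary))
  }

  if ("couinaud" %in% stages) {
    if (is.null(out$veins)) stop("stage 'couinaud' requires vein identification")
    say("Couinaud partition")
    cou <- inStage("couinaud", couinaudFromVeins(liver, out$veins))
    out$couinaud <- cou
    report$couinaud <- list(
      planes = lapply(cou$planes, function(p)
        list(orientation = p@orientation,
             coefficients = as.numeric(p@coefficients))),
      volumesMl = as.list(cou$volumesMl))
  }

  if (!is.null(reference) && !is.null(humanErrors) && !is.null(liver)) {
    rep <- evaluateSegmentation(liver, reference, humanErrors)
    out$evaluation <- rep
    report$evaluation <- list(metrics = as.list(rep@metrics),
                              scores = as.list(rep@scores),
                              totalScore = rep@totalScore)
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(out$liver))
      writeMask(out$liver, file.path(outDir, "liver.mhd"))
    if (!is.null(out$nodules))
      writeMask(out$nodules, file.path(outDir, "nodules.mhd"))
    if (!is.null(out$vessels))
      writeMask(out$vessels, file.path(outDir, "vessels.mhd"))
    if (!is.null(out$veins))
      writeLabelVolume(out$veins$labelVolume,
                       file.path(outDir, "veins.mhd"))
    if (!is.null(out$couinaud))
      writeLabelVolume(out$couinaud$labels,
                       file.path(outDir, "couinaud.mhd"))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out$report <- report
  out
}
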