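## Real-coded genetic algorithm for the five level-set parameters.
##
## Each individual carries five genes (minRMS, gLow, gHigh, beta, gamma);
## fitness of a gene vector is F = 100 - aggregated total score of the
## segmentations it produces against the references, so minimizing F
## maximizes agreement. Selection is fitness-proportional with elitism of
## one; crossover is arithmetic; mutation is Gaussian perturbation clipped
## to the gene ranges. Crossover, mutation and steady-state rates
## interpolate linearly from their initial to final values across the
## generations, and a second sequenced experiment restarts the search with
## a fraction of its population seeded from the first experiment's best.

geneNames <- c("minRMS", "gLow", "gHigh", "beta", "gamma")

#' Genetic-algorithm configuration
#'
#' Defaults follow the configuration used to tune the liver segmentation:
#' 30 generations, population 30, crossover rate 0.8 -> 0.65, mutation rate
#' 0.1 -> 0.8, steady-state rate 0.8 -> 0.2, 2 sequenced experiments with a
#' seed rate of 0.1 between them. Default gene ranges bracket the values
#' that segment livers satisfactorily: minRMS [0.005, 0.05], gLow and gHigh
#' [0.1, 0.7], beta [0.5, 50] (positive expands, see [levelSetParams()]),
#' gamma [0, 1000].
#'
#' @param nGenerations,populationSize GA size.
#' @param crossoverRate,mutationRate,steadyStateRate numeric(2): initial and
#'   final rate, linearly interpolated across generations. The steady-state
#'   rate is the fraction of the population carried over unchanged each
#'   generation.
#' @param nExperiments number of sequenced experiments.
#' @param seedRate fraction of the next experiment's initial population
#'   copied from the previous experiment's best individuals.
#' @param ranges named list of numeric(2) per gene.
#' @param aggregation `"mean"` or `"min"` of per-exam scores.
#' @param seed RNG seed.
#' @return list of class `"gaConfig"`.
#' @export
gaConfig <- function(nGenerations = 30L, populationSize = 30L,
                     crossoverRate = c(0.8, 0.65),
                     mutationRate = c(0.1, 0.8),
                     steadyStateRate = c(0.8, 0.2),
                     nExperiments = 2L, seedRate = 0.1,
                     ranges = list(minRMS = c(0.005, 0.05),
                                   gLow = c(0.1, 0.7),
                                   gHigh = c(0.1, 0.7),
                                   beta = c(0.5, 50),
                                   gamma = c(0, 1000)),
                     aggregation = c("mean", "min"), seed = 1L) {
  aggregation <- match.arg(aggregation)
  rates <- list(crossoverRate, mutationRate, steadyStateRate)
  if (any(vapply(rates, function(r)
    length(r) != 2 || any(r < 0) || any(r > 1), TRUE)))
    stop("rates must be numeric(2) within [0, 1]")
  if (populationSize < 2L) stop("populationSize must be >= 2")
  if (!identical(sort(names(ranges)), sort(geneNames)))
    stop("ranges must name exactly the five genes")
  if (any(vapply(ranges, function(r)
    !all(is.finite(r)) || r[1] >= r[2], TRUE)))
    stop("each range must be finite with low < high")
  structure(list(nGenerations = as.integer(nGenerations),
                 populationSize = as.integer(populationSize),
                 crossoverRate = crossoverRate, mutationRate = mutationRate,
                 steadyStateRate = steadyStateRate,
                 nExperiments = as.integer(nExperiments),
                 seedRate = seedRate, ranges = ranges[geneNames],
                 aggregation = aggregation, seed = as.integer(seed)),
            class = "gaConfig")
}

#' Segmentation fitness for a training set
#'
#' Builds the fitness function the GA minimizes: for a gene vector it runs
#' [segmentLiver()] on every training exam, scores each result against its
#' reference with [totalScore()], aggregates across exams (mean or min) and
#' returns `F = 100 - aggregate`. A failed segmentation contributes a score
#' of 0 for its exam. Results are cached by the gene tuple rounded to 6
#' decimals, since the GA revisits genotypes.
#'
#' @param trainingSet list of exams, each a list with elements `volume`
#'   ([CTVolume-class]), `initSliceIndex`, `initMask2d` and `reference`
#'   ([VoxelMask-class]).
#' @param refs a [humanErrorRefs()].
#' @param aggregation `"mean"` or `"min"`.
#' @return function(genes) -> F in [0, 100].
#' @export
segmentationFitness <- function(trainingSet, refs,
                                aggregation = c("mean", "min")) {
  aggregation <- match.arg(aggregation)
  if (!length(trainingSet)) stop("empty training set")
  cache <- new.env(parent = emptyenv())
  function(genes) {
    key <- paste(sprintf("%.6f", genes), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    params <- levelSetParams(minRMS = genes[["minRMS"]],
                             gLow = genes[["gLow"]], gHigh = genes[["gHigh"]],
                             beta = genes[["beta"]], gamma = genes[["gamma"]])
    scores <- vapply(trainingSet, function(exam) {
      res <- try(segmentLiver(exam$volume, exam$initSliceIndex,
                              exam$initMask2d, params), silent = TRUE)
      if (inherits(res, "try-error") || maskVoxelCount(res) == 0)
        return(0)
      rep <- try(evaluateSegmentation(res, exam$reference, refs),
                 silent = TRUE)
      if (inherits(rep, "try-error")) 0 else rep@totalScore
    }, 0)
    f <- 100 - if (aggregation == "mean") mean(scores) else min(scores)
    cache[[key]] <- f
    f
  }
}

#' Evaluate one gene vector's fitness on a training set
#'
#' @param genes named numeric of the five genes.
#' @inheritParams segmentationFitness
#' @return F = 100 - aggregated score (lower is better).
#' @export
evaluateFitness <- function(genes, trainingSet, refs,
                            aggregation = c("mean", "min")) {
  segmentationFitness(trainingSet, refs, aggregation)(genes[geneNames])
}

interpRate <- function(rate, gen, nGen) {
  if (nGen <= 1) return(rate[1])
  rate[1] + (rate[2] - rate[1]) * (gen - 1) / (nGen - 1)
}

#' Run the genetic parameter search
#'
#' @param cfg a [gaConfig()].
#' @param fitness function(named numeric genes) -> scalar F to minimize.
#'   Use [segmentationFitness()] for the segmentation objective or supply a
#'   surrogate.
#' @return list with `best` (list of `genes` and `fitness`) and `history`
#'   (data.frame: experiment, generation, bestF, meanF). The best F within
#'   each experiment is non-increasing (elitism).
#' @export
runGA <- function(cfg, fitness) {
  stopifnot(inherits(cfg, "gaConfig"), is.function(fitness))
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  }, add = TRUE)
  set.seed(cfg$seed)

  lows <- vapply(cfg$ranges, `[`, 0, 1)
  highs <- vapply(cfg$ranges, `[`, 0, 2)
  nGene <- length(geneNames)
  randomIndividual <- function()
    setNames(runif(nGene, lows, highs), geneNames)
  evalPop <- function(pop) vapply(pop, fitness, 0)

  history <- list()
  overallBest <- NULL
  carryover <- list()
  for (exp in seq_len(cfg$nExperiments)) {
    pop <- replicate(cfg$populationSize, randomIndividual(),
                     simplify = FALSE)
    if (length(carryover)) {
      nSeed <- min(length(carryover), cfg$populationSize)
      pop[seq_len(nSeed)] <- carryover[seq_len(nSeed)]
    }
    fit <- evalPop(pop)
    for (gen in seq_len(cfg$nGenerations)) {
      cr <- interpRate(cfg$crossoverRate, gen, cfg$nGenerations)
      mr <- interpRate(cfg$mutationRate, gen, cfg$nGenerations)
      ssr <- interpRate(cfg$steadyStateRate, gen, cfg$nGenerations)

      ord <- order(fit)
      nKeep <- max(1L, round(ssr * cfg$populationSize))
      keepIdx <- ord[seq_len(nKeep)]       # elite carried over unchanged
      newPop <- pop[keepIdx]

      # fitness-proportional selection on (maxF - F)
      w <- max(fit) - fit + 1e-9
      while (length(newPop) < cfg$populationSize) {
        parents <- sample.int(length(pop), 2L, prob = w / sum(w),
                              replace = TRUE)
        p1 <- pop[[parents[1]]]; p2 <- pop[[parents[2]]]
        child <- if (runif(1) < cr) {
          lam <- runif(nGene)
          lam * p1 + (1 - lam) * p2
        } else p1
        mut <- runif(nGene) < mr
        if (any(mut))
          child[mut] <- child[mut] +
            rnorm(sum(mut), 0, 0.1 * (highs[mut] - lows[mut]))
        child <- pmin(pmax(child, lows), highs)
        newPop[[length(newPop) + 1L]] <- setNames(child, geneNames)
      }
      newFit <- c(fit[keepIdx], evalPop(newPop[-seq_len(nKeep)]))
      pop <- newPop; fit <- newFit
      history[[length(history) + 1L]] <- data.frame(
        experiment = exp, generation = gen, bestF = min(fit),
        meanF = mean(fit))
    }
    bestIdx <- which.min(fit)
    expBest <- list(genes = pop[[bestIdx]], fitness = fit[bestIdx])
    if (is.null(overallBest) || expBest$fitness < overallBest$fitness)
      overallBest <- expBest
    nSeed <- max(1L, round(cfg$seedRate * cfg$populationSize))
    carryover <- pop[order(fit)[seq_len(nSeed)]]
  }
  list(best = overallBest, history = do.call(rbind, history))
}
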