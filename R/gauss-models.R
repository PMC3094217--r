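## Gaussian and three-component mixture estimation on intensity histograms.
##
## The intra-liver histogram is modelled as H = G_l + G_c + G_r: a dominant
## central parenchyma Gaussian, a darker nodule component on the left and a
## brighter vessel component on the right. The decomposition exploits the
## dominance of the central component: it is isolated by symmetric
## completion around the histogram mode, subtracted, and the side components
## are recovered from the residual mass below and above the mode before a
## joint refinement of all parameters.

FWHM_TO_SIGMA <- 2 * sqrt(2 * log(2))  # 2.3548...

# initial (K, mu, sigma) for a Levenberg-Marquardt Gaussian fit:
# K = max count, mu = argmax, sigma = FWHM / 2.3548 with the FWHM taken by
# linear interpolation at half maximum
gaussianInit <- function(mids, counts) {
  imax <- which.max(counts)
  K <- counts[imax]; mu <- mids[imax]
  half <- K / 2
  bw <- if (length(mids) > 1) mids[2] - mids[1] else 1
  crossing <- function(idx) {
    # idx walks away from the peak; find first drop below half and
    # interpolate the crossing abscissa
    for (j in seq_along(idx)[-1]) {
      if (counts[idx[j]] <= half) {
        c1 <- counts[idx[j - 1]]; c2 <- counts[idx[j]]
        f <- if (c1 > c2) (c1 - half) / (c1 - c2) else 0.5
        return(abs(mids[idx[j - 1]] - mu) + f * bw)
      }
    }
    abs(mids[idx[length(idx)]] - mu) + bw / 2
  }
  wl <- if (imax > 1) crossing(imax:1) else bw / 2
  wr <- if (imax < length(mids)) crossing(imax:length(mids)) else bw / 2
  sigma <- max((wl + wr) / FWHM_TO_SIGMA, bw / 4)
  c(K = K, mu = mu, sigma = sigma)
}

#' Fit a Gaussian to a histogram by Levenberg-Marquardt least squares
#'
#' Minimizes the sum of squared residuals between the bin counts and
#' `K * exp(-(x - mu)^2 / (2 sigma^2))`. Initialization takes the peak
#' count, its abscissa and a FWHM-derived width; the returned fit never has
#' a larger residual than this initialization.
#'
#' @param h an [IntensityHistogram-class] with at least 3 nonzero bins (a
#'   degenerate single-bin histogram yields a sigma-floored model flagged
#'   `"degenerate"`).
#' @return A [GaussianModel-class].
#' @examples
#' x <- 50:150
#' h <- new("IntensityHistogram", mids = x,
#'          counts = 50 * exp(-(x - 100)^2 / (2 * 10^2)))
#' fitGaussian(h)
#' @export
fitGaussian <- function(h) {
  stopifnot(is(h, "IntensityHistogram"))
  nz <- sum(h@counts > 0)
  bw <- if (length(h@mids) > 1) h@mids[2] - h@mids[1] else 1
  init <- gaussianInit(h@mids, h@counts)
  if (nz < 3) {
    # width is indeterminate on a collapsed histogram; floor it at a few
    # bins so downstream threshold ranges keep a workable scale
    return(gaussianModel(init[["K"]], init[["mu"]], max(init[["sigma"]], 5 * bw),
                         flag = "degenerate"))
  }
  df <- data.frame(x = h@mids, y = h@counts)
  fit <- try(minpack.lm::nlsLM(
    y ~ K * exp(-(x - mu)^2 / (2 * sigma^2)), data = df,
    start = list(K = init[["K"]], mu = init[["mu"]], sigma = init[["sigma"]]),
    lower = c(0, min(h@mids) - diff(range(h@mids)), bw / 10),
    upper = c(10 * max(h@counts), max(h@mids) + diff(range(h@mids)),
              2 * diff(range(h@mids)) + bw),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(gaussianModel(init[["K"]], init[["mu"]], init[["sigma"]],
                         flag = "degenerate"))
  }
  cf <- coef(fit)
  cand <- gaussianModel(max(cf[["K"]], 0), cf[["mu"]], abs(cf[["sigma"]]))
  rss <- function(g) sum((h@counts - gaussianValue(g, h@mids))^2)
  initModel <- gaussianModel(init[["K"]], init[["mu"]], init[["sigma"]])
  if (rss(cand) <= rss(initModel)) cand else initModel
}

#' Parenchyma thresholds from a Gaussian model
#'
#' The low/high thresholds are the abscissae where the unit-amplitude
#' Gaussian takes the pre-defined values `gLow` (below the mean) and
#' `gHigh` (above the mean):
#' `T_L = mu - sigma * sqrt(-2 log gLow)`, `T_H = mu + sigma * sqrt(-2 log gHigh)`.
#'
#' @param g a [GaussianModel-class].
#' @param gLow,gHigh Gaussian low/high factors, each in (0, 1).
#' @return Named numeric `c(low =, high =)` with `low < high`.
#' @export
thresholdsFromGaussian <- function(g, gLow, gHigh) {
  stopifnot(is(g, "GaussianModel"))
  if (gLow <= 0 || gLow >= 1 || gHigh <= 0 || gHigh >= 1)
    stop("Gaussian factors must lie strictly inside (0, 1)")
  c(low = g@mu - g@sigma * sqrt(-2 * log(gLow)),
    high = g@mu + g@sigma * sqrt(-2 * log(gHigh)))
}

# mirror a histogram's counts around the bin index of `center` (a bin
# center value); out-of-range reflections count as zero
mirrorCounts <- function(mids, counts, center) {
  bw <- if (length(mids) > 1) mids[2] - mids[1] else 1
  i0 <- round((center - mids[1]) / bw) + 1
  j <- as.integer(round(2 * i0 - seq_along(mids)))
  ok <- j >= 1 & j <= length(mids)
  out <- numeric(length(mids))
  out[ok] <- counts[j[ok]]
  out
}

# centered moving average (odd window), zero-padded at the ends
movingAverage <- function(v, window = 5L) {
  if (window <= 1L) return(v)
  half <- window %/% 2L
  out <- numeric(length(v))
  for (k in -half:half) {
    idx <- seq_along(v) + k
    ok <- idx >= 1 & idx <= length(v)
    out[ok] <- out[ok] + v[idx[ok]]
  }
  out / window
}

# fit a side component from residual mass restricted to one side of the
# mode, symmetrically completed around the residual's own peak.
#
# Numerical guards (see the methods vignette): residual bins within 1.5
# central sigmas of the central mean are dominated by subtraction noise
# under sampling and are excluded, and the residual is lightly smoothed
# (5-bin moving average) before peak detection and fitting. The symmetric
# smoothing leaves the component mean unbiased, and the joint refinement on
# the raw histogram removes the small width bias it introduces.
fitSideComponent <- function(mids, residual, xmax, side, gc, rawCounts) {
  Kc <- gc@K
  keep <- if (side == "left") mids < xmax else mids > xmax
  r <- pmax(residual, 0)
  # within 2 central sigmas the residual is dominated by subtraction noise
  # and by the censoring pileup a threshold-bounded liver mask leaves near
  # T_L/T_H; neither is a tissue class
  r[!keep | abs(mids - gc@mu) < 2 * gc@sigma] <- 0
  r <- movingAverage(r, 5L)
  absent <- function(mu0)
    gaussianModel(0, mu0, 1, flag = "absent")
  peakBin <- which.max(r)
  # absence floor: relative to the dominant component, and to the Poisson
  # scale of the raw counts at the candidate peak (a bump compatible with
  # counting noise is not a tissue class)
  noiseFloor <- 5 * sqrt(rawCounts[peakBin] + 1)
  if (sum(r > 0) < 3 || max(r) < 0.01 * Kc || max(r) < noiseFloor)
    return(absent(xmax + if (side == "left") -1 else 1))
  xmaxSide <- mids[peakBin]
  hSide <- pmax(r, mirrorCounts(mids, r, xmaxSide))
  g <- fitGaussian(new("IntensityHistogram", mids = mids, counts = hSide))
  if (g@K < 0.01 * Kc) absent(g@mu) else g
}

#' Decompose an intra-liver histogram into a three-Gaussian mixture
#'
#' Executes four steps in order, exploiting the dominance of the central
#' (parenchyma) component: (1) the central component is isolated as
#' `H_c(x) = min(H(x), H(2 x_max - x))` — the minimum between points
#' symmetric about the mode — and fitted; (2) the nodule component is fitted
#' to the symmetric completion of the residual mass below the mode; (3) the
#' vessel component likewise from the residual above the mode; (4) all
#' parameters of the present components are refitted jointly. Components are
#' returned ordered by mean; a side component with negligible amplitude or
#' fewer than 3 supporting residual bins is flagged `"absent"`.
#'
#' @param h an [IntensityHistogram-class] of the voxels inside the segmented
#'   liver.
#' @return A [MixtureModel-class].
#' @export
decomposeMixture <- function(h) {
  stopifnot(is(h, "IntensityHistogram"))
  mids <- h@mids; counts <- h@counts
  # the mode is located on a lightly smoothed histogram: mirroring around a
  # mode displaced by sampling noise skews the whole central fit
  xmax <- mids[which.max(movingAverage(counts, 5L))]

  ## step 1: central component by symmetric minimum around the mode
  hc <- pmin(counts, mirrorCounts(mids, counts, xmax))
  gc <- fitGaussian(new("IntensityHistogram", mids = mids, counts = hc))

  ## step 2: left (nodule) component from the residual below the mode;
  ## subtracting the fitted central component realises "excluding G_c from
  ## the initial histogram"
  resid1 <- counts - gaussianValue(gc, mids)
  gl <- fitSideComponent(mids, resid1, xmax, "left", gc, counts)

  ## step 3: right (vessel) component from what remains above the mode
  resid2 <- resid1 - gaussianValue(gl, mids)
  gr <- fitSideComponent(mids, resid2, xmax, "right", gc, counts)

  ## step 4: joint refinement of all present components
  refit <- refineMixture(mids, counts, gl, gc, gr)
  gl <- refit$gl; gc <- refit$gc; gr <- refit$gr

  mixtureModel(left = gl, centre = gc, right = gr)
}

refineMixture <- function(mids, counts, gl, gc, gr) {
  haveL <- gl@flag != "absent"; haveR <- gr@flag != "absent"
  df <- data.frame(x = mids, y = counts)
  model <- function(p, x) {
    v <- p[["Kc"]] * exp(-(x - p[["muc"]])^2 / (2 * p[["sc"]]^2))
    if (haveL) v <- v + p[["Kl"]] * exp(-(x - p[["mul"]])^2 / (2 * p[["sl"]]^2))
    if (haveR) v <- v + p[["Kr"]] * exp(-(x - p[["mur"]])^2 / (2 * p[["sr"]]^2))
    v
  }
  start <- list(Kc = gc@K, muc = gc@mu, sc = gc@sigma)
  if (haveL) start <- c(start, list(Kl = gl@K, mul = gl@mu, sl = gl@sigma))
  if (haveR) start <- c(start, list(Kr = gr@K, mur = gr@mu, sr = gr@sigma))
  bw <- if (length(mids) > 1) mids[2] - mids[1] else 1
  rng <- diff(range(mids))
  lower <- vapply(names(start), function(n)
    if (startsWith(n, "K")) 0 else if (startsWith(n, "s")) bw / 10
    else min(mids) - rng, 0)
  upper <- vapply(names(start), function(n)
    if (startsWith(n, "K")) 10 * max(counts) else if (startsWith(n, "s"))
      2 * rng + bw else max(mids) + rng, 0)
  resFun <- function(p) {
    p <- as.list(p)
    counts - model(p, mids)
  }
  fit <- try(minpack.lm::nls.lm(
    par = start, fn = resFun, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
  if (!inherits(fit, "try-error")) {
    p <- as.list(coef(fit))
    rssNew <- sum(resFun(p)^2)
    rssOld <- sum(resFun(start)^2)
    if (rssNew <= rssOld) {
      gc <- gaussianModel(p$Kc, p$muc, abs(p$sc))
      if (haveL) gl <- gaussianModel(p$Kl, p$mul, abs(p$sl))
      if (haveR) gr <- gaussianModel(p$Kr, p$mur, abs(p$sr))
    }
  }
  # re-apply the absence floor after refinement
  if (haveL && gl@K < 0.01 * gc@K)
    gl <- gaussianModel(0, gl@mu, gl@sigma, flag = "absent")
  if (haveR && gr@K < 0.01 * gc@K)
    gr <- gaussianModel(0, gr@mu, gr@sigma, flag = "absent")
  # enforce mean ordering: a side component that drifted across the centre
  # is not a credible tissue class
  if (gl@flag != "absent" && gl@mu >= gc@mu)
    gl <- gaussianModel(0, gc@mu - 1, gl@sigma, flag = "absent")
  if (gr@flag != "absent" && gr@mu <= gc@mu)
    gr <- gaussianModel(0, gc@mu + 1, gr@sigma, flag = "absent")
  list(gl = gl, gc = gc, gr = gr)
}

# intersection abscissa of two Gaussians strictly between their means,
# solved from the log-equality quadratic with a grid-scan fallback
gaussianIntersection <- function(g1, g2) {
  lo <- min(g1@mu, g2@mu); hi <- max(g1@mu, g2@mu)
  if (hi - lo < 1e-12)
    stop("mixture degeneracy: components share a mean, no intersection between means")
  a <- 1 / (2 * g2@sigma^2) - 1 / (2 * g1@sigma^2)
  b <- g1@mu / g1@sigma^2 - g2@mu / g2@sigma^2
  cc <- g2@mu^2 / (2 * g2@sigma^2) - g1@mu^2 / (2 * g1@sigma^2) +
    log(g1@K / g2@K)
  roots <- if (abs(a) < 1e-14) {
    if (abs(b) < 1e-14) numeric() else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric()
    else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  roots <- roots[roots > lo & roots < hi]
  if (length(roots) == 1) return(roots)
  if (length(roots) > 1) return(roots[which.min(abs(roots - (lo + hi) / 2))])
  # fallback: scan |difference| on a fine grid between the means
  xs <- seq(lo, hi, length.out = 4001)[-c(1, 4001)]
  dif <- abs(gaussianValue(g1, xs) - gaussianValue(g2, xs))
  xs[which.min(dif)]
}

# largest (side = left) or smallest (side = right) abscissa at which the
# side component's share of the two-component density reaches `proportion`;
# bin-grid scan refined by bisection to 1e-3 of a grid step
ratioThreshold <- function(gSide, gCentre, side, proportion, searchRange) {
  share <- function(x) {
    s <- gaussianValue(gSide, x); c0 <- gaussianValue(gCentre, x)
    s / (s + c0)
  }
  step <- 1
  xs <- seq(searchRange[1], searchRange[2], by = step)
  ok <- share(xs) >= proportion
  if (!any(ok))
    stop("mixture degeneracy: side component never reaches the required proportion")
  xEdge <- if (side == "left") max(xs[ok]) else min(xs[ok])
  # refine the crossing between xEdge (inside) and its outward neighbour
  a <- xEdge
  b <- if (side == "left") xEdge + step else xEdge - step
  if (b >= searchRange[1] && b <= searchRange[2] && share(b) < proportion) {
    for (i in 1:20) {
      m <- (a + b) / 2
      if (share(m) >= proportion) a <- m else b <- m
      if (abs(a - b) < 1e-3 * step) break
    }
  }
  a
}

#' Region-growing thresholds from a mixture model
#'
#' For the left (nodule) side, returns `low` = the largest intensity at
#' which the nodule component accounts for at least `proportion` of the
#' nodule+parenchyma density (seed threshold) and `high` = the intersection
#' abscissa of the nodule and parenchyma Gaussians (acceptance threshold).
#' For the right (vessel) side, `low` = the intersection of the vessel and
#' parenchyma Gaussians and `high` = the smallest intensity at which the
#' vessel component reaches `proportion` of the vessel+parenchyma density.
#'
#' @param m a [MixtureModel-class]; both relevant components must be present.
#' @param side `"left"` (nodules) or `"right"` (vessels).
#' @param proportion density-share level defining the seed threshold
#'   (default 0.70).
#' @return Named numeric `c(low =, high =)` with `low < high`.
#' @export
growThresholds <- function(m, side = c("left", "right"), proportion = 0.70) {
  stopifnot(is(m, "MixtureModel"))
  side <- match.arg(side)
  if (proportion <= 0.5 || proportion >= 1)
    stop("proportion must lie in (0.5, 1)")
  gc <- m@centre
  g <- if (side == "left") m@left else m@right
  if (g@flag == "absent" || gc@flag == "absent")
    stop("both components must be present to derive growing thresholds")
  cross <- gaussianIntersection(g, gc)
  if (side == "left") {
    tl <- ratioThreshold(g, gc, "left", proportion,
                         c(g@mu - 6 * g@sigma, cross))
    th <- cross
  } else {
    tl <- cross
    th <- ratioThreshold(g, gc, "right", proportion,
                         c(cross, g@mu + 6 * g@sigma))
  }
  if (tl >= th) stop("mixture degeneracy: threshold ordering violated")
  c(low = tl, high = th)
}
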