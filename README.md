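# hepatoseg

Semi-automatic segmentation of the liver and its internal structures from
abdominal CT, for surgical planning. Starting from a rough manual
delineation on a single axial slice, the package extracts the liver, its
vessels and adipose nodules, identifies the hepatic and portal veins, and
partitions the organ into the eight Couinaud functional segments — the
anatomical units a hepatic surgeon resects.

## The method

Four stages run sequentially:

1. **Liver** — a 2D level set per axial slice, propagated both superiorly
   and inferiorly, each slice seeded with its neighbour's result. The
   parenchyma is modelled per slice by a Gaussian fitted
   (Levenberg–Marquardt) to the intensity histogram inside the current
   initial solution; two thresholds are placed where the unit-amplitude
   Gaussian reaches the factors G_L and G_H:

   T_L = μ − σ √(−2 ln G_L),  T_H = μ + σ √(−2 ln G_H)

   The speed image is piecewise linear, P(x) = g(x) − T_L below the
   threshold midpoint and T_H − g(x) above it: positive (expansion) inside
   [T_L, T_H], negative (shrinkage) outside, zero at the learned
   boundaries. The field evolves as
   φ ← φ − Δt (β P |∇φ| − γ Z κ |∇φ|), with κ the mean curvature and Z the
   positive part of P rescaled to [0, 1], so smoothing loses importance
   near boundaries. There is no advection term. Slice-wise hole filling
   merges enclosed vessels and nodules; propagation stops in a direction
   when the contour vanishes. Five parameters (minimum RMS, G_L, G_H, β,
   γ) default to values tuned by a genetic search against reference
   segmentations: 0.0209, 0.3859, 0.2809, 5.1929 (positive expands, see
   `?levelSetParams`), 217.414.

2. **Nodules and vessels** — the intra-liver histogram is decomposed into a
   three-Gaussian mixture H = G_l + G_c + G_r (nodules / parenchyma /
   vessels) by exploiting the dominance of G_c: symmetric min-completion
   around the mode isolates G_c, the side components come from the residual
   mass below and above the mode, and a joint refit polishes all
   parameters. Dual-threshold region growing segments each class: seeds
   where one component holds ≥ 70 % of the pairwise density, acceptance up
   to the components' intersection.

3. **Veins** — the three main hepatic branches are tracked from the most
   superior vessel slice by maximal footprint overlap, accepted when taller
   than 15 % of the liver height, and labelled right / middle / left by a
   clock rule on their coronal projections. The portal vein is the largest
   remaining component; other residuals merge into touching branches or
   become auxiliary vessels.

4. **Couinaud** — one near-vertical least-squares plane per hepatic branch
   (x = a·y + b·z + c) and one near-horizontal plane through the portal
   vein (z = a·x + b·y + c) cut the liver into 4 lateral slabs × 2
   (superior / inferior) = 8 regions.

Segmentations are evaluated with the five standard disparity metrics — VOE,
RVD (%), ASD, RMSSD, MSD (mm) — each scored on a human-error-anchored scale
(100 = perfect, 75 = mean inter-observer error, linear, clamped at 0); the
mean of the five scores is the fitness the genetic tuner (`runGA`)
maximizes when re-estimating the level-set parameters on a training set.

Because no CT exam ships with the package, a seeded phantom generator
(`makePhantom`) produces liver-like volumes with known ground truth:
near-Gaussian parenchyma (100 ± 15), three bright hepatic tubes and a
portal trunk (160 ± 10), dark nodules (40 ± 10), short distractor vessels,
an adjacent iso-intense confounder and a reconstruction-like point-spread
blur. Stress presets reproduce the method's two documented failure modes
(`"big-nodule"`, `"peripheral-nodule"`).

## Worked example

```r
library(hepatoseg)

ph <- makePhantom(phantomSpec(shape = c(64, 96, 96), seed = 7))
z  <- 32
truth <- voxelData(ph$liver)[z, , ]
init  <- truth                      # erode to ~60 % as a rough manual seed
while (sum(init) > 0.6 * sum(truth))
  init <- EBImage::erode(init, EBImage::makeBrush(3, "box"))

res <- runPipeline(ph$volume, z, matrix(as.integer(init), 96, 96))

refs <- humanErrorRefs(voe = 6.4, rvd = 4.7, asd = 1.0, rmssd = 1.8,
                       msd = 19.0)
evaluateSegmentation(res$liver, ph$liver, refs)
#> MetricReport
#>   VOE       7.9522 %   score   68.94
#>   RVD      -7.9522 %   score   57.70
#>   ASD       0.8811 mm  score   77.97
#>   RMSSD     1.6041 mm  score   77.72
#>   MSD      10.0000 mm  score   86.84
#>   total score 73.83

res$mixture
#> MixtureModel (left=nodules, centre=parenchyma, right=vessels)
#>   left   K=27.9699 mu=41.5229 sigma=9.56933 [ok]
#>   centre K=1527.8 mu=99.8385 sigma=14.9739 [ok]
#>   right  K=63.4677 mu=155.296 sigma=11.1928 [ok]

res$couinaud$labels
#> LabelVolume 64 x 96 x 96 (z,y,x)
#>   1 (VII (right posterior superior)): 6349 voxels
#>   2 (VI (right posterior inferior)): 87 voxels
#>   3 (VIII (right anterior superior)): 16423 voxels
#>   4 (V (right anterior inferior)): 6758 voxels
#>   5 (IVa (medial superior, I proxy)): 15639 voxels
#>   6 (IVb (medial inferior)): 7906 voxels
#>   7 (II (left superior)): 6237 voxels
#>   8 (III (left inferior)): 329 voxels
```

Reading the output: the liver was recovered with a volumetric overlap
error of 8 % and sub-millimetre average surface distance against the
phantom truth; the mixture found the three intensity classes within a bin
or two of the generating means (40 / 100 / 160); and the four fitted
planes cut the liver into all eight Couinaud regions, whose voxel counts
become resection volumes in ml in `res$report$couinaud$volumesMl`.

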