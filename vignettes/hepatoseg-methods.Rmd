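---
title: "hepatoseg: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hepatoseg: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic phantom does and does not emulate, and the numerical decisions
taken where the design was genuinely open. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The segmentation model and its assumptions

The pipeline rests on two anatomical working hypotheses: the liver
parenchyma is roughly homogeneous in CT intensity, and the liver's veins
and nodules lie mainly inside the organ. Everything else follows from
them.

**Liver.** Segmentation is slice-wise 2D, not 3D: each axial slice is
seeded with the adjacent slice's result and the parenchyma intensity law
is re-estimated on every slice, which is what makes the method robust to
the intensity drift between and within exams. On a slice, a Gaussian
$K e^{-(x-\mu)^2/2\sigma^2}$ is fitted to the histogram of the current
initial region; thresholds are placed where the *unit-amplitude* Gaussian
reaches the configured factors, $T_L = \mu - \sigma\sqrt{-2\ln G_L}$ and
$T_H = \mu + \sigma\sqrt{-2\ln G_H}$. The speed image is piecewise linear
in the intensity $g$: $P = g - T_L$ below the threshold midpoint,
$P = T_H - g$ above it, so the contour expands over parenchyma and stalls
exactly at the learned boundaries. The level-set field (signed distance,
negative inside) evolves with a propagation term $\beta P |\nabla\varphi|$
and a curvature term $\gamma Z \kappa |\nabla\varphi|$, where $Z$ is the
positive part of $P$ rescaled to $[0,1]$ — smoothing deliberately loses
force near boundaries so fine boundary detail is not blurred away. No
advection term is used: liver boundaries cannot be told from neighbouring
soft tissue reliably enough to anchor one.

**Nodules and vessels.** Inside the segmented liver three intensity
classes are assumed: adipose nodules darker than parenchyma, vessels
brighter. The histogram is decomposed as $H = G_l + G_c + G_r$ under the
dominance assumption $K_c \gg K_l, K_r$: the central component is isolated
by taking, at each intensity, the minimum of the histogram and its mirror
around the mode; the side components are reconstructed from the residual
mass below (nodules) and above (vessels) the mode by symmetric completion
around the residual's own peak; a final joint Levenberg–Marquardt refit
polishes all parameters on the raw histogram. Region growing then uses a
strict seed threshold (the intensity at which the side component holds at
least 70 % of the side+centre density) and a looser acceptance threshold
(the intersection of the two Gaussians). Only nodules darker than
parenchyma (adipose) are in scope.

**Veins.** Three main hepatic branches are assumed (the arrangement in
roughly 80 % of people), running predominantly vertically from the upper
liver. Tracking is deliberately simple — per-slice maximal footprint
overlap, no bifurcation analysis — and a candidate is accepted as a main
branch when it spans more than 15 % of the liver height. Branches are
labelled right/middle/left by their clockwise order around the thorax
axis in coronal projection; the portal vein is the largest connected
component left after removing the branches.

**Couinaud.** The partition is purely geometric: a near-vertical
least-squares plane per hepatic branch and a near-horizontal plane
through the portal vein. The parameterizations $x = ay + bz + c$ and
$z = ax + by + c$ enforce the orientation classes and are always solvable
by ordinary least squares. Eight plane-bounded regions result. This
construction cannot isolate the caudate lobe (segment I, defined by the
cava vein, which the method does not see); the medial–superior slab is
only a loose proxy, and its legend entry says so.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `minRMS` | 0.0209 | level-set units/iter | convergence threshold on the RMS field change over interface cells |
| `gLow` (G_L) | 0.3859 | — (0,1) | Gaussian factor placing T_L |
| `gHigh` (G_H) | 0.2809 | — (0,1) | Gaussian factor placing T_H |
| `beta` | +5.1929 | per intensity unit | propagation weight; positive expands inside [T_L, T_H] under this package's sign convention |
| `gamma` | 217.414 | — | curvature weight, modulated by Z ∈ [0,1] |
| grow `proportion` | 0.70 | — | seed-threshold density share for region growing |
| `minHeightFraction` | 0.15 | — | branch acceptance rule vs liver height |

The five level-set defaults are the values found by the genetic search on
a five-exam training corpus. The propagation weight is printed there as
−5.1929; its sign is convention-bound (it depends on which way the signed
distance and the update are oriented), so this package fixes its own
convention — positive β expands — and ships +5.1929. Sensible search
ranges for re-tuning (`gaConfig()`): minRMS [0.005, 0.05], G_L and G_H
[0.1, 0.7], β [0.5, 50], γ [0, 1000], bracketing the regions reported to
perform well (minRMS 0.01–0.03, G_L 0.3–0.5, G_H 0.2–0.5, γ up to ~1000).

The GA itself: 30 generations × 30 individuals, crossover 0.8→0.65,
mutation 0.1→0.8, steady-state 0.8→0.2, two sequenced experiments with
10 % seeding between them. Where the original configuration left
semantics open we chose: rates interpolate *linearly* across generations
(the minimal assumption for an initial/final pair); the steady-state rate
is the fraction of the population carried over unchanged; selection is
fitness-proportional on (maxF − F) with elitism of one. The objective is
F = 100 − (aggregated total score), so minimizing F maximizes agreement —
the scores-to-F transformation is our reconciliation of "minimize the
fitness" with "fitness is a mean of agreement scores".

Human-error references for scoring are configuration, never defaulted:
they belong to a reference corpus, not to the method.

## The phantom: what it emulates, what it does not

`makePhantom()` builds an ellipsoid-like liver with near-Gaussian
parenchyma (100 ± 15), three bright near-vertical hepatic tubes that
converge superiorly, a near-horizontal portal trunk entering mid-liver,
dark spherical nodules, short bright distractor blobs (auxiliary
vessels), an optional adjacent confounder blob with overlapping
intensities (95 ± 15, separated from the liver by a thin fat-like gap),
and additive noise. Class intensities are drawn white and then blurred
in-plane with a σ = 0.5 voxel kernel emulating the reconstruction
point-spread function; draw widths are inflated by the kernel's measured
white-noise attenuation (1/0.6434) so the *observable* voxel
distributions match the stated class laws. The blur matters twice over:
real CT intensities are spatially correlated, and the partial-volume ramp
at edges is precisely what a threshold-driven contour needs in order to
stop cleanly — a voxelwise-independent phantom is not just unrealistic,
it pins the front on speckle.

Default geometry at 96×128×128 voxels, 2×1×1 mm: hepatic tubes spanning
45 % of the liver height (comfortably above the 15 % acceptance rule),
two distractors at ~5 % height, two interior nodules. Stress presets:
`"big-nodule"` (a nodule of volume comparable to the parenchyma with a
darker structure touching the liver — the histogram stops being Gaussian
and the fitted thresholds admit a leak) and `"peripheral-nodule"` (a dark
nodule straddling the boundary — outside [T_L, T_H] and not enclosed, so
hole filling cannot recover it).

What the phantom does *not* emulate: Hounsfield calibration, beam
hardening and reconstruction physics, organ deformation, contrast phases,
anatomical variation in vessel topology (always 3 branches + 1 trunk),
and neighbouring organs with *contact* over large surfaces (the
confounder is a single blob). Tests passing on the phantom therefore
establish internal correctness of the algorithms under the method's own
assumptions, not clinical performance.

## Numerical choices

*Level set.* Explicit upwind scheme (Osher–Sethian switches), central
differences for curvature with $|\kappa|$ clamped at 1/h (sharper bends
are grid artefacts), updates restricted to a ±6 voxel band,
reinitialization to a signed distance every 10 iterations (so the front,
moving ≤ 0.45 voxel per iteration, cannot escape the band between
reinitializations), and the signed distance lightly blurred (σ = 0.7) to
keep the curvature estimate smooth across the distance transform's
voxel-scale kinks. The time step is the dense-solver Courant rule
Δt = 0.45 / max|update|. The speed image is clamped symmetrically at its
maximum positive value before weighting: far from the thresholds only the
sign of P matters, and unclamped background magnitudes would throttle the
time step to no benefit. Convergence is declared when the RMS change over
the interface cells (|φ| ≤ 1) stays below `minRMS` for three consecutive
iterations, or when no voxel changes membership across a full
reinitialization cycle — the discrete interface is then stationary
whatever the sub-voxel jitter of the field.

*Per-slice refit guard.* The slice-wise Gaussian refit assumes the seed
still samples parenchyma. When a refitted mean departs from the running
parenchyma model by more than 3σ, or the width changes more than
threefold, the refit is rejected and the running model kept. Without the
guard, a seed that has drifted past the organ's poles re-centres the
thresholds on whatever tissue it lands on and the "vanished contour" stop
can never fire; with it, the contour meets purely negative speed beyond
the organ and collapses, which is exactly the documented termination
behaviour.

*Gaussian fits.* Levenberg–Marquardt (via `minpack.lm`), initialized at
the histogram peak with σ = FWHM/2.3548 (FWHM by linear interpolation at
half maximum); the returned fit never has a larger residual than this
initialization. A collapsed (single-bin) histogram gets a 5-bin σ floor
and a `"degenerate"` flag — the width is indeterminate there, and the
floor keeps the speed image at a workable scale.

*Mixture decomposition.* The mode is located on a 5-bin-smoothed
histogram (mirroring around a noise-displaced mode skews the entire
central fit). Side residuals subtract the *fitted* central Gaussian, are
zeroed within 2 central σ of the central mean (subtraction noise and the
censoring pileup a threshold-bounded liver mask leaves near T_L/T_H live
there, and neither is a tissue class), and are 5-bin smoothed before peak
detection; symmetric smoothing leaves component means unbiased and the
joint refit on the raw histogram removes the small width bias. A side
component is declared absent when its peak falls below 1 % of the central
amplitude, below 5√(count) at its peak bin (compatible with counting
noise), or has fewer than 3 supporting bins. The left component is
reconstructed from the residual *below* the mode — the only reading
consistent with nodules being darker than parenchyma. Threshold searches
use the density ratio (not cumulative counts) on a unit grid refined by
bisection to 10⁻³; Gaussian intersections solve the log-equality
quadratic, keeping the root strictly between the means, with a grid scan
fallback.

*Region growing* is 3D with 26-connectivity by default (thin oblique
vessels fragment under 6-connectivity); threshold comparisons are strict
inequalities. Hole filling is 2D per slice with 4-connected background,
matching the slice-wise pipeline and preventing 3D tunnels from blocking
the fill.

*Vein tracking.* "First slice containing vessels" is the most superior
one (the branches run top-down); the posterior slice in the overlap walk
is the next inferior slice. Overlap ties break by larger component, then
smaller centroid x. Processed candidates — accepted or rejected — are
permanently removed from seeding, guaranteeing termination. Heights are
measured in mm (slices × z-spacing) against the liver height in mm, so
anisotropic spacing cannot skew the 15 % rule. The clock is viewed from
anterior with 12 o'clock superior and its centre at the liver centroid (a
proxy for the thorax axis, configurable); the patient's right lies at
negative x. Branch masks, portal and auxiliary vessels partition the
input vessel mask exactly.

*Couinaud.* Side tests use signed residuals of the plane equations at
voxel centres in mm; voxels exactly on a plane go to the right/inferior
side, deterministically. The slab-code → numeral mapping (VII/VI,
VIII/V, IVa/IVb, II/III from right to left, superior/inferior) follows
the standard segment chart; it is a documented convention of this
package, as is the "IVa (I proxy)" caveat.

*Metrics.* Border voxels are mask voxels with a 6-neighbour outside (the
volume edge counts as outside); distances are Euclidean between voxel
centres in mm, symmetrized over both border sets, with nearest neighbours
located by a chunked quadratic expansion and then recomputed by direct
difference for machine-precision accuracy. The volumetric overlap error
is reported in its error form, 100·(1 − |∩|/|∪|); the volume difference
is kept signed and its absolute value used for scoring; scores clamp at
zero.

## Problem sizes

The test suite exercises the full pipeline at the phantom's native
96×128×128 resolution (about half a minute end to end) and uses scaled
48×64×64 or 64×96×96 phantoms for properties that do not need the full
grid — multi-seed loops, equivariance checks, idempotence. Mixture
recovery is verified at n = 200 000 histogram samples over 10 seeds;
metric and flood-fill oracles run on 12³–16³ volumes where brute force is
exact and fast.

## Known limitations

- The liver contour stops at the fitted intensity thresholds, so a
  partial-volume rim of roughly one voxel remains outside; overlap error
  scales with surface/volume and is correspondingly larger on small
  livers and coarse grids.
- Peripheral dark nodules are excluded (outside [T_L, T_H], not enclosed,
  hence unrecoverable by hole filling), and a nodule with volume
  comparable to the parenchyma breaks the single-Gaussian heuristic and
  can cause leaks into adjacent darker structures — both are reproduced
  deliberately by the stress presets and asserted in the tests.
- Leaks toward structures in *contact* with the liver across a wide front
  (e.g. mediastinum-like geometry) are not prevented; barriers/advection
  are out of scope.
- Anatomies with other than three hepatic branches are returned as found
  and flagged; the Couinaud stage requires all three.
- Hyperdense lesions and contrast-phase handling are out of scope, as are
  curved (non-planar) segment boundaries.
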