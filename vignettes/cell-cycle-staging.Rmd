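---
title: "Staging the cell cycle from 3D nuclear images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging the cell cycle from 3D nuclear images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Fixed interphase cells stained with DAPI carry, in principle, enough
information to stage the cell cycle: DNA content doubles between G1 (2N)
and G2 (4N), integrated nuclear DAPI intensity is roughly proportional to
DNA content, and nuclei grow as cells progress. `cellcyclekit` implements
a complete pipeline for exploiting this: ground-truth labeling from a
Fucci reporter line, classical morphometry with SVM baselines, and a 3D
convolutional network (with a 2D variant and a continuous-angle regression
variant) that predicts G1 versus S/G2 from the DAPI channel alone.

Because real two-platform imaging datasets are hundreds of gigabytes, the
package also ships a synthetic Fucci image simulator. Every stage of the
pipeline is exercised, end to end, on simulated tiles whose per-nucleus
ground truth is known by construction.

# Ground-truth labeling from the Fucci reporter

In the Fucci2a system, mCherry-hCdt1 (RFP, written $R$) accumulates during
G1 and mVenus-hGeminin (GFP, written $G$) during S/G2, so the per-nucleus
balance of the two reporters labels the stage. Labels are only trustworthy
after three exclusion filters, applied in this order; each excluded cell
records the first filter that caught it, but the *surviving set* is
order-invariant because a cell is excluded iff it meets at least one
criterion:

1. **Low intensity** — the cell does not express the reporter:
   $\mu_R < 1500$ or $\mu_G < 2200$ (epifluorescence);
   $\mu_R < 700$ or $\mu_G < 2000$ (confocal). All comparisons strict.
2. **Ratio** — the cell is transitioning between phases:
   $0.9 < \mu_G'/\mu_R' < 1.1$ (open interval) after per-channel
   normalization.
3. **Volume** — abnormal size (debris, doublets):
   $|V - \mu_V| > 2.5\,\sigma_V$ (strict).

Survivors are labeled G1 if $R > G$ and S/G2 if $R < G$; an exact tie is
an error, since ties cannot survive the ratio filter under equal channel
normalizers. The continuous alternative is the angle
$\theta = \operatorname{atan2}(G, R)$ in degrees: 0° is deep G1, 90° late
S/G2, and 45° the $R = G$ boundary.

Two details are genuinely open choices and are implemented as follows:

* **Ratio-filter normalization.** The normalizers are the per-channel
  medians of the mean intensities over cells passing the low-intensity
  filter. A median is robust to the non-expresser tail and scale-matches
  the two channels, which have different brightness distributions. Both
  normalizers are reported in the labeling output.
* **Volume statistics population.** $\mu_V, \sigma_V$ are computed over
  the same low-intensity-passing population, before ratio filtering:
  "abnormal size" is a statement about expressing cells. This is
  configurable at the call site.

# Quality control and quantification

Instance masks come from any external 3D segmenter and are consumed at
full resolution. Object QC removes (a) objects touching a tile face and
(b) objects with solidity < 0.9, where solidity = voxel count / convex
volume. Convex volume follows the regionprops convention: the number of
voxel centers inside or on the convex hull of the object's voxel centers.
(Measuring the hull's polytope volume instead would make a convex solid
score above 1 — a $10^3$ cube has hull volume $9^3$ — so the lattice-count
convention is the one under which "solidity $\le 1$" holds.) The hull
itself is computed by quickhull with integer-exact orientation predicates:
voxel coordinates are small integers, so every $3\times3$ difference
determinant is exact in double precision and no geometric epsilon exists
anywhere in the package.

Per-nucleus features are voxel-exact sums and counts; axis lengths use the
ellipsoid-equivalent convention $4\sqrt{\lambda}$ on the eigenvalues of
the voxel-coordinate covariance (population normalization). Single-nucleus
crops are windows of $150\times150\times90$ (X, Y, Z) centered on the
rounded centroid (ties toward negative infinity), with non-object voxels
zeroed. The masked-crop convention makes conservation exact — the crop
integrates to the object's aggregate intensity — and matches the
normalization step, which presupposes a zero background.

# Morphology features and surface area

2D features are measured on the Z maximum-intensity projection of the
masked crop (so the 2D support is exactly the projected 3D mask): 2D
integrated intensity, area, convex area, bounding-box area, equivalent
diameter $\sqrt{4A/\pi}$, extent, maximum Feret diameter (largest distance
between hull vertex centers), solidity. 3D features add volume, convex
volume, bounding-box volume, surface area and sphericity
$\pi^{1/3}(6V)^{2/3}/A$.

Surface area needs care on binary voxel data: any isosurface of the raw
binary mask follows the blocky voxel boundary, and we measured a ~9%
overestimate for a radius-10 rasterized sphere with marching cubes (~28%
with marching tetrahedra); the corresponding sphericities (0.91, 0.78) are
badly biased. The implementation therefore smooths the zero-padded binary
mask with a small Gaussian ($\sigma = 0.8$ voxel) and triangulates the 0.5
level set by marching tetrahedra with linear interpolation. On rasterized
spheres with $r \ge 8$ this is accurate to about 1–2% (sphericity 1.003 at
$r = 10$). Residual discretization can still push sphericity of
near-perfect spheres slightly above 1; such values are clamped to 1 with a
warning rather than reported. $\sigma$ trades smoothing bias against voxel
noise: much larger values visibly shrink small objects (at $\sigma = 2$
the $r=6$ sphere loses >20% of its area).

All geometry is in voxel units. The SVMs z-score every feature (fit on
training rows only), which removes global unit scaling, so physical-unit
calibration is deliberately out of scope.

# SVM baselines

The baselines are RBF-kernel SVMs (via `e1071`/libsvm) with z-scored
features. Hyperparameters are selected by nested cross-validation:
candidate regularization strengths $C \in \{0.1, 1, 10, 100\}$ and kernel
widths $\gamma \in \{10^{-3},\dots,10\}$ (log-spaced), scored by mean
inner-fold AUROC on the training rows only, then refit on all training
rows. These grid ranges are package choices: they are standard, span four
orders of magnitude, and keep a full panel run within seconds at desk
scale. ROC analysis uses the decision value (margin) — AUROC is rank-based
and calibration-free. S/G2 is the positive class everywhere.

# The convolutional models

The 3D classifier is a four-block volumetric encoder with an aggressive
global-pooling head:

| block | unit channels | unit structure |
|-------|---------------|----------------|
| B1 | 1 → 16 → 32 | GroupNorm → 3×3×3 conv (no bias) → ReLU, twice |
| B2 | 32 → 32 → 64 | idem |
| B3 | 64 → 64 → 128 | idem |
| B4 | 128 → 128 → 256 | idem |

with 2×2×2 max pooling between blocks and a head of adaptive max-pool to
$1^3$ → flatten → dropout 0.5 → affine 256 → 1. Group normalization uses 8
channel groups (1 when the unit input has fewer than 8 channels; epsilon
$10^{-5}$). The first unit of each block halves the block's output width
except where that would drop below the input width. This fixes the
parameter total at exactly **1,757,267** (14,290 / 83,072 / 332,032 /
1,327,616 / 257 per part), which the test suite asserts.

The 2D variant uses four *single*-unit blocks 1 → 32 → 64 → 128 → 256
whose convolutions carry a bias, with the identical head: exactly
**388,547** parameters. A double-unit bias-free 2D stack cannot reach that
total (it gives 586,547), so the single-unit biased composition is the one
this package defines as the 2D architecture.

The classification head reads the output scalar as a logit (binary
cross-entropy loss); the regression head reads it as the angle $\theta$ in
degrees (mean-squared-error loss — the loss that RMSE reporting implies).
Both heads share every parameter shape, so checkpoints are
interchangeable up to interpretation, and an external encoder checkpoint
can be injected by parameter name (`loadEncoderWeights()`).

**Engine.** No deep-learning framework is assumed: layers are implemented
in the package as im2col gathers (C kernels) feeding BLAS GEMMs, with
hand-derived backward passes. Backward convolutions choose between a
gather route (correlate the output gradient with the flipped,
channel-transposed kernel) and a scatter route (col2im of $\delta W^T$),
whichever moves fewer values. The test suite validates every layer's
gradient against central finite differences to $10^{-5}$ relative error
and the convolution against a direct dense correlation.

**Training recipe.** Adam with learning rate $10^{-5}$, weight decay
$10^{-1}$ (applied as L2 on the gradient), batch size 4; random Z-rotation
augmentation (uniform 0–359°, bilinear, zero fill) on training samples
when enabled; per-epoch validation with the best-accuracy (classification)
or best-RMSE (regression) checkpoint retained, ties resolved toward the
earlier epoch. The reference schedule is 800 epochs; desk-scale runs in
the test suite use 30. The accuracy threshold is probability 0.5, both for
checkpoint selection and for reported accuracy.

# Preprocessing contract

Crops are block-mean downsampled (anti-aliased, intensity-conserving up to
edge effects) by platform-specific factors — (2, 2, 1) in (X, Y, Z) for
epifluorescence, (2, 2, 2) for confocal, chosen to roughly isotropize each
platform's voxel — then divided by a single normalization constant (the
median over training crops of each crop's median nonzero intensity) and
zero-padded, centered with odd remainders trailing, to 75×75×90 (X, Y, Z).
Both platform paths end at exactly (Z, Y, X) = (90, 75, 75). The
training-crop medians description fixes two ambiguities deliberately: the
*median*-based statistic is used (it is the operational definition even
where a mean is named), and training crops are divided by the same global
constant as validation/test crops so scales stay comparable across splits
(a per-crop alternative is available as a flag).

The 70/20/10 split uses seeded uniform sampling with largest-remainder
rounding (no stratification by default; a label-stratified option exists).
The split manifest records ids, assignments, the seed and the
normalization constant, so no-leakage audits are mechanical: the constant
is recomputable from the training ids alone, and merged multi-platform
datasets concatenate items without moving any id across splits, keeping
per-source normalization constants.

# The synthetic data generator

Nuclei are ellipsoids with lognormal semi-axes and intensities, placed
without overlap by rejection sampling (conservative bounding spheres) and
rendered as constant-density solids plus a flat background offset and
additive Gaussian read noise, clipped to the camera bit depth. There is no
optical PSF, photobleaching or tiling overlap — the pipeline never
deconvolves, so optics would add cost without exercising any code path.
Coordinates are (Z, Y, X) throughout, matching planewise TIFF page order.

Three presets define the study conditions (all ratios are S/G2 relative to
G1):

* **default** — DNA density ×1.6 (lognormal sd 0.15 on the log scale),
  volume ×1.3 (sd 0.2); G1 draws RFP ≫ GFP (medians 12,000 / 6,000),
  S/G2 the reverse (5,000 / 15,000), each with sd 0.2; class prior 0.54
  G1. The ×1.6/×1.3 pair approximates the 2N→4N DNA doubling integrated
  over an asynchronous S/G2 population, and reproduces the
  larger-and-brighter-is-S/G2 structure with realistic overlap.
* **easy** — density ×2.0, volume ×1.6, spreads tightened to 0.1, used by
  the scaled-down learnability checks.
* **anisoz** — both classes share the XY footprint; S/G2 is elongated
  ×1.5 along Z only, with DNA density ×1.25 at spread 0.25. Max
  projections lose the Z extent, so this preset separates what 3D
  features add over 2D ones.

Injected pathologies exercise the labeling filters: *non-expressers* draw
both reporter means near 300–400 (far below every threshold), and
*extreme volumes* multiply a cell's volume by ~5 (tight spread 0.05,
one-sided large — merged doublets and debris clumps are big). The margin
analysis behind the ×5 choice: with normal volumes lognormal (sd 0.2)
around class means 1 and 1.3, a 3% extreme fraction shifts the population
mean to ≈1.28 and inflates $\sigma_V$ to ≈0.83, putting the
2.5$\sigma$ band top near 3.4× baseline; the smallest extreme draw sits
near 4.8× and the largest normal cell crosses the band with probability
below $10^{-3}$ per thousand-cell dataset. The injected flags and the
mean/SD filter therefore agree exactly with high margin, which is what
makes truth-table comparisons meaningful. A `borderFraction` knob places
some nuclei within one semi-axis of a tile face to give border QC real
work.

The generator's truth table records every drawn parameter, the rendered
voxel count, and a `flag_low` column evaluated from the *drawn* reporter
means against the profile thresholds — the measured means sit above the
drawn ones by the (small) background offset, and all intensity
distributions keep a wide margin around the thresholds, so drawn and
measured verdicts coincide.

What the simulator does **not** emulate — PSF blur, chromatin texture,
mitotic morphologies, segmentation errors other than border truncation —
bounds what passing tests show: they validate the pipeline's logic,
conservation properties and learnability on idealized nuclei, not
performance on real microscope data.

# Desk-scale choices and limitations

The test suite runs the full pipeline at reduced scale: miniature tiles
(96×96×64 voxels, isotropic 400 nm), 32³ crops downsampled to 16³ network
inputs (16 is the smallest admissible input: four pooling stages), 200
nuclei and 30 epochs for the learnability checks. These sizes are the
package's own test-design choices; the user-facing defaults remain the
full 150×150×90 → 75×75×90 pipeline. Known limitations: training at the
full 75×75×90 scale in R is possible but slow (the engine is tuned for
the scaled volumes); the volume filter inherits the non-robustness of
mean/SD statistics under heavy contamination (by design, to match the
published filter); and the 2D architecture is fixed by its parameter
total rather than by layer-for-layer symmetry with the 3D network, as
discussed above.
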