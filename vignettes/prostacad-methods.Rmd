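---
title: "prostacad: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{prostacad: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This note records the scientific and numerical decisions behind the
package: what the synthetic cohort does and does not emulate, how the
cascade is defined and trained, how the evaluation statistics are
computed, and where design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## Coordinate and storage conventions

Volumes are arrays indexed `(x, y, z)` with +x the patient's left, +y
posterior, and axial slices stored cranial-first: slice 1 is the most
superior. Two consequences are used throughout: the "more cranial"
tie-break of key-image selection is the *smaller* slice index, and the
sextant "base" band (the superior part of the gland, under the bladder)
has the smallest indices while "apex" has the largest. World coordinates
come from the voxel-to-world affine (origin, spacing, direction) carried
by every `volume_grid`; NIfTI sform rows and DICOM geometry tags map
onto it directly.

## The synthetic cohort

Each phantom is an analytic scene rendered onto voxel grids, so the same
patient can be produced consistently on deliberately mismatched grids
(the `deranged_geometry` flag shifts and rotates the T2 grid by ~3 mm and
4° to give the rigid registration real work).

* **Gland** — a superellipsoid (exponent 2.5) with per-patient semi-axes
  drawn around 22 × 17 × 19 mm, a size typical of the biopsy-referral
  population. The exponent gives flatter, more prostate-like posterior
  curvature than a pure ellipsoid and a nontrivial apex–base profile for
  sextant tests.
* **Zones** — the peripheral zone is the posterior part of the outer
  radial shell (fractional thickness 0.4); the central gland is the
  complement within the gland, so PZ ∪ CG = gland and PZ ∩ CG = ∅ holds
  by construction and is re-checked per case.
* **Lesions** — ellipsoids with the major axis in-plane and axis ratios
  1 : 0.7 : 0.55, placed by rejection sampling inside the configured
  zone; per-patient multiplicity follows the cohort table
  (112:173:49:10:3 for 0..4 lesions), the PZ/TZ split is 212/313, and
  the greatest dimension follows a truncated normal with *truncated*
  moments 1.6 ± 0.7 cm, truncated below at 0.4 cm.
* **Intensities** — piecewise-constant tissue means plus Gaussian noise
  per sequence. On ADC (arbitrary units close to 10⁻⁶ mm²/s scaling):
  background 400, CG 1150, PZ 1500, lesion 700, noise sd 80 — lesions
  are markedly hypointense, as csPCa is. On T2 the lesion sits slightly
  below the zones; on high-b DWI the gland is bright against background
  and lesions brighter still, which is what the K-means localizer
  exploits.

**Lesion-size sampler.** The cohort table reports the mean ± sd of
*observed* (hence truncated-positive) sizes, so 1.6/0.7 are treated as
moments of the truncated law and the underlying normal parameters are
solved by moment matching (closed-form truncated moments + BFGS) at
configuration time. Plugging 1.6/0.7 into the untruncated normal would
inflate the truncated mean to 1.667 cm. The acceptance target draws
5,000 sizes, renders each mask at the acquisition resolution
(0.75 × 0.75 × 4 mm) and measures axis-aligned extents, which adds a
voxelization error bounded by about one in-plane voxel.

**What a green test does not establish.** The phantom has no bias field,
no k-space artifacts, no benign mimics (hyperplastic nodules caused most
of the reference system's false positives), lesion contrast is constant
rather than grade-dependent, and anatomy is convex. Toy-scale recovery
therefore demonstrates that the pipeline's plumbing, losses, matching
rules and bookkeeping are correct — not clinical performance.

## Preprocessing

* **Registration** resamples T2WI onto the ADC/DWI grid using the header
  transforms only (rigid, as scanner series are temporally close).
  Images use third-order B-spline interpolation with the standard
  recursive prefilter (pole √3−2, mirror boundaries; the exact
  full-period initialization matters for short axes — without it,
  identity resampling is off by ~1e-3). Masks use Gaussian label
  interpolation: smooth the indicator at σ = 0.5 voxel, resample
  linearly (no overshoot), threshold at 0.5 — output stays binary.
* **Localization** runs K-means (k = 2, intensity-only, 3 restarts,
  seeded) on the central half of the high-b DWI field of view, keeps the
  brightest cluster, opens with a radius-1 ball, retains the largest
  26-connected component and dilates its bounding box by 5 mm. k = 2 and
  intensity-only features are the simplest scheme meeting the contract;
  both are configurable.
* **Crop** is per-slice 2D (pseudo-3D): every axial slice is cropped
  identically to a `patch_size`² window centered on the box centroid,
  zero-padded at edges, with the inverse placement recorded so
  predictions map back losslessly.
* **Normalization** is min–max to [0, 1] per patient per sequence over
  the cropped region (the prostate ROI), not the whole volume; constant
  patches map to zero.
* **Augmentation** applies one mirror/rotation draw to images and masks
  identically (rotation uniform within ±10°, cubic for images, nearest
  for masks so they stay binary) and adds uniform per-pixel noise within
  ±0.001 to images only.

## Network and training

The Res-UNet is a 2D encoder–decoder whose levels are residual blocks:
main path two (3×3 conv → batch norm → ReLU), a 1×1 conv shortcut,
addition, ReLU. Downsampling is 2×2 max pooling, upsampling
nearest-neighbour + 3×3 conv, skips are concatenations, and the head is
a 1×1 conv with a logistic output. Unstated hyperparameters default to
canonical choices (depth 4, base width 32, widths doubling), all
overridable in `network_spec`. The "weighted" qualifier of the source
architecture is never defined there; the package exposes an optional
per-pixel loss-weight map (uniform by default) rather than inventing a
scheme.

Forward and backward passes are hand-written over compiled kernels and
verified by central finite differences (block-level agreement ~1e-9;
note that zero-initialized biases put dead-feature pixels exactly on the
ReLU kink, where the loss is genuinely non-differentiable — the
full-network gradient check perturbs biases slightly to stay off that
measure-zero set). The head bias starts at −2 so sparse-target training
does not open with a violent all-background correction.

**Loss.** The training default is per-sample soft Dice plus
cross-entropy with positive pixels weighted ×10. Two failure modes of
plain batch-pooled soft Dice motivated this: pooled Dice lets large
lesions drown out small ones, and on ~1%-foreground targets pure Dice
has a strong all-background local optimum into which the toy networks
reliably collapse (observed: loss ≈ lesion-slice fraction, zero
supra-threshold pixels). The cross-entropy term keeps per-pixel
gradients alive through sigmoid saturation. Plain pooled Dice
(`"dice_global"`) and BCE remain available by config, and the
*evaluation* DSC is always the plain pooled formula
2|X∩Y|/(|X|+|Y|).

**Stage conditioning.** Training conditions stages 2 and 3 on
ground-truth masks (teacher forcing); inference uses the predicted
masks. Stage-3 slice sampling is balanced — all lesion-bearing slices
plus at most as many lesion-free gland slices per case — because the raw
slice distribution is so skewed that the lesion network otherwise never
leaves the background optimum at toy scale. Validation uses a seeded
*random* case split: cohorts are ordered by status, so a tail split
would yield a single-class validation set and make best-checkpoint
selection meaningless (a bug caught by exactly that symptom during
development).

Reference training defaults (batch 20, lr 1e-4, 120 epochs, Adam,
threshold 0.5, patch 128) are the package defaults; the test suite runs
scaled-down worlds (depth-2, width-8 networks, 1.5–2 mm in-plane grids,
patch 32–40, lr 1e-3, a few epochs) to fit single-CPU budgets. Scale is
the only thing reduced; distributions and rules are not.

## Inference post-filters

Predicted PZ is clipped to the predicted gland and CG is the voxelwise
difference, so the zone algebra holds for every output. Lesion maps are
thresholded at 0.5, optionally (default on) intersected with the gland,
and 26-connected components below 25 mm³ are discarded. Clinical-scale
CAD descriptions are typically silent on false-positive suppression;
these two declared filters are the smallest defensible ones and both are
configurable.

## Evaluation statistics

* **Per-lesion rule**: the overlap denominator is the ground-truth
  lesion's area on the slice (reading "overlapping ≥50% of the manual
  lesions" as a fraction of the manual lesion), boundary inclusive.
  One truth lesion may be matched by several predicted components (its
  DSC is then computed against their union), and a predicted blob
  spanning two truth lesions counts for each — both conventions noted in
  the match table.
* **Confidence intervals** are exact Clopper–Pearson in beta-quantile
  form. Of the reference tables' printed bounds, all but a handful agree
  to one decimal; the exceptions differ by one unit in the last digit
  (rounding style) except one bound (41/41 → printed 96.4) that no
  standard interval reproduces and that recomputes to 91.4; the
  acceptance test asserts the recomputed value.
* **McNemar**: exact two-sided binomial tail below 25 discordant pairs,
  continuity-corrected chi-square otherwise; no multiplicity adjustment
  (the reference analysis applies none).
* **Sextants** divide each patient's *occupied gland span* (not the image
  volume) into equal-thickness thirds, crossed with a left/right split
  at the gland centroid's sagittal plane; equal thirds are a declared
  choice where anatomical landmarks are unavailable. Lesion-to-sextant
  assignment in reports reuses the evaluation rule, so report and
  metrics cannot disagree.

## Degenerate inputs and tie-breaks

DSC of two empty masks is defined as 1.0 and flagged; one empty mask
gives 0. Constant localizer input raises an error rather than guessing.
Constant patches normalize to zero. Key-image ties break cranially. A
lesion whose sextant-rule hit set is empty (possible for tiny lesions
predicted at the gland border) falls back to the sextant holding most of
it, so every reported lesion carries ≥1 sextant label. Max-pool argmax
ties take the first-scanned element; all randomness flows from explicit
seeds, so runs are bit-reproducible.

## Known limitations

2D slice-wise modelling (no through-plane context), rigid registration
only, no bias-field or artifact simulation, no benign-mimic modelling,
no FROC analysis, no DICOM writing, and no attempt to reproduce
clinical-cohort performance figures, which were measured on private
patient data.
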