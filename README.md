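# prostacad

Fully automated detection and localization of clinically significant
prostate cancer (csPCa, Gleason score ≥ 7) on biparametric prostate MRI —
an ADC map plus T2-weighted imaging — implemented end to end in R.

## Who this is for

Researchers building or evaluating prostate-MRI computer-aided detection
who want a complete, self-contained reference pipeline: a synthetic
cohort generator with exact ground truth, the preprocessing chain used by
clinical CAD systems, a trainable cascaded segmentation model, the
lesion/sextant/patient evaluation framework used in radiology validation
studies, and machine-readable structured reports. Everything runs on one
CPU with no external deep-learning runtime: the residual U-Net's forward
and backward passes are compiled into the package.

## The model

The cascade decomposes multi-class segmentation into three binary
problems following prostate anatomy:

1. **Gland**: a 2D residual U-Net takes the image channels (ADC + T2WI,
   or ADC alone) and segments the whole prostate.
2. **Peripheral zone**: a second network takes images + gland mask and
   segments the PZ (clipped to the gland). The central gland is the set
   difference, CG = gland \ PZ.
3. **Lesion**: a third network takes images + PZ + CG masks and segments
   csPCa, thresholded at 0.5, intersected with the gland and filtered by
   a minimum component volume.

Each resolution level is a residual block — two (3×3 conv → batch norm →
ReLU) on the main path, a 1×1 conv shortcut, addition and ReLU — with
max-pool downsampling, nearest-neighbour upsampling, long skip
connections, and a logistic 1×1 head. Training uses Adam (batch 20,
learning rate 1e-4, 120 epochs by default) with a per-sample soft Dice +
weighted cross-entropy loss.

Evaluation implements the standard validation rules: a predicted lesion
is a true positive when it covers ≥ 50% of a ground-truth lesion's area
on at least one axial slice; a sextant (left/right × apex/mid/base)
contains a lesion when it holds ≥ 50% of the lesion or the lesion fills
≥ 50% of the sextant; a patient is positive when any lesion is detected.
Rates carry exact Clopper–Pearson 95% intervals; detectors are compared
with the McNemar test (exact below 25 discordant pairs).

## Worked example

```r
library(prostacad)

# a small synthetic cohort (coarse grid so it runs in seconds)
cfg <- phantom_config(shape = c(80, 80, 12), spacing = c(1.5, 1.5, 4),
                      seed = 11)
cohort <- sample_cohort(cfg, n_pos = 44, n_neg = 16)
pp <- lapply(cohort, preprocess_case,
             loc_cfg = localizer_config(patch_size = 40))

spec <- cascade_spec(variant = "bp",
  net_specs = lapply(1:3, function(i) network_spec(1, depth = 2,
                                                   base_width = 8)))
s3 <- train_stage(3, pp, spec,
                  train_config(batch = 20, lr = 1e-3, epochs = 14,
                               augment = FALSE, seed = 3))
tail(s3$history, 1)
#>    epoch       loss val_dsc
#> 14    14 0.06658146   0.928
```

The per-epoch `loss` is the training value of the combined soft-Dice +
weighted cross-entropy objective; `val_dsc` is the pooled thresholded
Dice of the lesion channel on the held-out validation split.

Trained this way on 60 phantoms (stages 1–3) and applied to 20 held-out
cases, the cascade reaches a whole-gland DSC of 0.989 and detects 14 of
17 lesions (82%) under the ≥50%-slice-overlap rule, with no
false-positive patients — the numbers the acceptance suite asserts. A
per-case structured report carries the status ("csPCa"/"non-csPCa"),
gland and lesion 3D diameters in mm, sextant localization, and a key
image:

```r
inf <- infer_case(pp[[1]], nets, spec)   # nets = trained stages 1..3
rp  <- build_report(pp[[1]], inf)
rp$status            # "csPCa"
rp$lesions[[1]]$sextants  # e.g. "left-mid"
```

Desk-checkable statistics come from the same code paths the pipeline
uses:

```r
100 * clopper_pearson(84, 88)
#>    lower    upper
#> 88.76908 98.74782      # printed as 95.5 (84/88) [88.8, 98.7]
mcnemar_test(c(rep(TRUE, 10), rep(FALSE, 2)),
             c(rep(FALSE, 10), rep(TRUE, 2)))$p_value
#> 0.03857422             # = 158/4096
```

## Layout

- `R/phantom.R` — synthetic biparametric cohort generator
- `R/preprocess.R` — registration, K-means localization, crop, normalize,
  augment
- `R/resunet.R`, `src/ops.cpp`, `R/train.R` — network, compiled kernels,
  training
- `R/cascade.R` — three-stage orchestration and lesion components
- `R/evaluate.R` — matching rules, rates, exact CIs, McNemar
- `R/report.R` — sextants, diameters, key images, structured reports
- `R/interface.R`, `inst/cli/prostacad` — pipeline driver and CLI
- `vignettes/prostacad-methods.Rmd` — the methods notes
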