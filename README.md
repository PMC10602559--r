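# zfcardio

Cardiac function analysis for larval zebrafish heart videos, and a scoring
layer for phenotypic drug screens built on it.

Zebrafish larvae with fluorescently labelled cardiomyocytes (e.g.
*Tg(cmlc2:eGFP)*) allow the beating heart to be filmed in vivo: a 2-second
video at 50 frames per second captures several cardiac cycles. This package
turns such videos into quantitative physiology. Per frame, the ventricle is
segmented (by a trainable neural network or a classical threshold
baseline); the mask sequence yields the time-varying ventricular area, from
which complete cardiac cycles are detected and the standard parameter set
is computed:

- **EDA, ESA** — end-diastolic / end-systolic projected ventricular area
  (pixels), the per-cycle maxima / minima of the area trace;
- **EDa, EDb, ESa, ESb** — long/short sides of the rotated minimum-area
  rectangle enclosing the ventricle at end-diastole / end-systole
  (rotating-calipers, pixels as unit squares);
- **FAC** = (EDA − ESA)/EDA × 100 — fractional area change (%);
- **FS** = (EDa − ESa)/EDa × 100 — fractional shortening (%);
- **SV** = 4/3 π (EDa·EDb² − ESa·ESb²) — stroke volume (pixel³; a
  halved-axes prolate-spheroid convention is also exposed);
- **HR** = cycles / duration × 60 — heart rate (beats/minute), with an
  independent neural estimator operating on the 1-D area trace.

For screening, each compound group is scored against control and
disease-model groups by the per-parameter **rescue index**
(X_drug − X_model)/(X_ctrl − X_model) on group means, averaged over the six
cardiac parameters plus a pericardial-edema flag into an **efficacy
score**; compounds scoring strictly above 0.7 are called hits and ranked.

Because no public labelled dataset exists for this problem, the package
includes a synthetic beating-heart simulator with exact closed-form ground
truth (masks, per-frame areas and axes, heart rate, FAC/FS), used both for
training data and as the oracle for the test suite. The two networks — a
U-Net-backbone segmenter with recurrent residual convolutional units,
two-level skip fusion, attention gates and an ASPP bottleneck, and a 1-D
CNN → inception → MLP heart-rate regressor — run on a compact reverse-mode
autodiff engine (R tape + C++ convolution kernels) shipped in the package
and verified by finite-difference gradient checks.

## Worked example

```r
library(zfcardio)

# a 2-s, 50-fps video of a ventricle beating at 150 bpm with 30% contraction
spec <- synth_heart_spec(hr_bpm = 150, contraction_frac = c(0.3, 0.3), seed = 8)
sim <- simulate_heart_video(spec)

# segment (classical baseline) and analyse
masks <- baseline_segment(sim$video)
params <- analyze_video(masks, fps = 50)
print(params)
#> cardiac_params: EDA=501.0 ESA=250.2 FAC=50.06% FS=31.25% SV=35554.5 HR=150.0 bpm edema=1 cycles=5 [ok]
```

The analytic truth for this specification is FAC = 51%, FS = 30%,
HR = 150 bpm: five complete cycles are found in 2 s (HR exact), and
FAC/FS land within a point of truth (the residual is rasterisation error
of the pixel masks).

A complete in-silico screen — control, disease model, and five compounds at
known rescue levels (1, 0.75, 0.5, 0.25, 0) — runs end to end through
simulation, segmentation, parameter extraction and scoring:

```r
scr <- simulate_screen(seed = 21)
res <- screen_compounds(scr$larvae, threshold = 0.7)
res[, c("rank", "compound", "efficacy_score", "n_parameters", "is_hit")]
#>   rank   compound efficacy_score n_parameters is_hit
#> 1    1 fullrescue      1.0000000            7   TRUE
#> 2    2       high      0.7290602            7   TRUE
#> 3    3        mid      0.4600050            7  FALSE
#> 4    4        low      0.1865059            7  FALSE
#> 5    5       null      0.0000000            7  FALSE
```

The full-rescue compound scores exactly 1 and the null compound exactly 0
(they reproduce the control/model groups), and the ranking recovers the
injected ordering of effect sizes.

Training the networks on synthetic data:

```r
frames <- make_seg_dataset(250, seed = 7)
sp <- split_dataset(frames, c(4, 1), seed = 7)          # 200 train / 50 val
seg <- train_segmenter(sp$train, sp$validation, seg_config(), epochs = 6, seed = 11)
tail(seg$history, 1)   # pooled validation IoU ~ 0.93

ds <- make_hr_dataset(500, bpm_range = c(60, 240), seed = 3)
hr <- train_hrnet(ds$traces, ds$bpm, seed = 5)
hr$metrics             # MAE ~ 1 bpm, r > 0.99 on held-out traces
```

A command-line interface wrapping these functions (subcommands `simulate`,
`train-seg`, `segment`, `analyze`, `train-hr`, `estimate-hr`, `eval-seg`,
`eval-hr`, `screen`, `run`) is installed at `inst/cli/zfcardio.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/zfcardio.R", package="zfcardio"))')" \
    analyze --video heart.tif --fps 50
```

See `vignettes/zfcardio-methods.Rmd` for the model assumptions, parameter
conventions (stroke-volume axis convention, cycle-boundary rules,
unit-square rectangles) and known limitations.

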