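---
title: "Methods: cardiac function analysis for larval zebrafish heart videos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiac function analysis for larval zebrafish heart videos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfcardio)
```

## The measurement problem

In transgenic zebrafish larvae with fluorescently labelled cardiomyocytes
(e.g. *Tg(cmlc2:eGFP)*), the beating heart can be filmed through the
transparent body wall. A short video — here 2 s at 50 frames per second, 100
frames — captures several complete cardiac cycles, and the projected
ventricle area over time carries most of the physiology of interest:

* **EDA / ESA** — the maximal (end-diastolic) and minimal (end-systolic)
  projected ventricular area within a cycle, in pixels.
* **EDa, EDb / ESa, ESb** — the long and short sides of the rotated
  minimum-area rectangle enclosing the ventricle at end-diastole /
  end-systole.
* **FAC** — fractional area change, `(EDA - ESA) / EDA * 100` (%).
* **FS** — fractional shortening, `(EDa - ESa) / EDa * 100` (%).
* **SV** — stroke volume, `4/3 * pi * (EDa * EDb^2 - ESa * ESb^2)`, an
  ellipsoid-volume difference (pixel^3; see "The stroke-volume axis
  convention" below).
* **HR** — heart rate, complete contraction cycles divided by video length,
  times 60 (beats/minute).

Manual extraction of these parameters is slow and unscalable, which is the
bottleneck this package removes: it segments the ventricle per frame,
converts the mask sequence into the parameters above, estimates heart rate
from the 1-D area signal, and scores compound effects in a phenotypic screen
of a drug-induced cardiomyopathy model.

## The synthetic beating heart

No public dataset of labelled larval heart videos accompanies this problem,
so the package ships a simulator whose ground truth is known in closed form,
and every downstream stage is validated against it.

A ventricle is modelled as a bright ellipse on a dim background. Its
semi-axes contract periodically as

\[ a(t) = a_0 (1 - c_a s(t)), \qquad b(t) = b_0 (1 - c_b s(t)), \]

where \(s(t) \in [0, 1]\) is the contraction waveform at frequency
`hr_bpm / 60` Hz, \(s = 0\) at end-diastole and \(s = 1\) at end-systole.
The default waveform is a raised cosine, `0.5 * (1 - cos(2 pi f t))`; real
ventricular dynamics are asymmetric (systole faster than diastole), so an
asymmetric variant with a configurable systolic fraction (default 0.35) is
also provided. The analytic consequences used as test oracles:

* projected area \( \pi a(t) b(t) \), so `EDA = pi a0 b0`,
  `ESA = pi a0 b0 (1 - ca)(1 - cb)`;
* `FAC = (1 - (1-ca)(1-cb)) * 100`, `FS = ca * 100`;
* `HR = hr_bpm` exactly, with `hr_bpm / 60 * n_frames / fps` full cycles in
  the video.

Rasterisation marks a pixel foreground iff its centre lies inside the
ellipse; for semi-axes of 8 px or more this keeps the pixel-count area
within 3% of \( \pi a b \), the tolerance the tests assert. The rendered
frame is mask-driven intensity (defaults: foreground 0.85, background 0.15
on a [0, 1] scale), an optional dimmer atrium blob beating in anti-phase,
Gaussian blur (default sigma 1 px), additive Gaussian noise (default sd
0.03), and optional per-frame centre jitter. Defaults follow the imaging
protocol the package targets — 100 frames at 50 FPS, 120 bpm, a 16 x 10 px
ventricle in a 64 x 64 px field, 25% axis contraction — with noise and blur
set to levels at which the classical baseline segmenter still works but is
visibly degraded, since no noise statistics of the original microscope are
published. What the simulator does **not** emulate: two-chamber anatomy with
shared walls, out-of-plane motion, photobleaching, pigment occlusion, or
blood-flow texture. Tests passing on synthetic data therefore validate the
geometry and signal-processing chain, not microscope-specific robustness.

The training-data protocol is implemented as first-class, tested code:
random train/validation split at an integer ratio (default 4:1; the
validation part is `floor(n / 5)`, the remainder trains), and augmentation
by random rotation (bilinear for images, nearest-neighbour for masks so they
stay binary), horizontal/vertical flips, and brightness/contrast factors
drawn from [0.9, 1.1]. `expand_training_set()` keeps the originals verbatim
and appends `factor - 1` augmented copies of each.

## Ventricle segmentation

`build_zvsegnet()` constructs a U-Net-backbone segmentation network with
four departures from the plain architecture:

1. **Recurrent residual convolutional units (RRCU)** replace the double
   convolutions: a 1x1 input projection followed by two recurrent 3x3
   convolutional layers, each unrolled for `rrcu_steps` iterations (default
   2) with shared weights, re-injecting the projected input at each step,
   and a residual connection around the pair.
2. **Two-level skip fusion**: each decoder level concatenates attention-gated
   features from its own encoder level *and* the adjacent one (pooled from
   the shallower level; for the topmost decoder, upsampled from level 2), so
   each decoder sees two receptive-field scales.
3. **Attention**: additive attention gates on the skip paths (decoder
   features gate encoder features through a single-channel sigmoid map) plus
   squeeze-and-excitation channel attention after each encoder/decoder
   block.
4. **ASPP bottleneck**: parallel 3x3 convolutions at dilations (1, 2, 4, 8),
   concatenated and fused by a 1x1 convolution.

The forward contract maps an H x W single-channel image (H, W divisible by
`2^depth`) to an H x W foreground probability map; `segment_video()` pads
inputs to the divisibility constraint by edge replication and crops the
result back. Channel widths start at `base_width` (default 8) and double
per level (default depth 2). These sizes, like the loss and optimiser, are
this package's own choices — the reference architecture's widths, loss and
training schedule are not published.

Training uses a Dice + binary cross-entropy loss (equal weights), the Adam
optimiser (learning rate 2e-3, batch 8), per-frame min-max input
normalisation, and keeps the best-on-validation-loss parameters. The
networks run on a compact reverse-mode automatic-differentiation engine
written for this package (an R tape over dense arrays with C++ im2col
convolution kernels); every operation's gradient is verified against
central finite differences in the test suite, and a whole-network check
asserts gradient flow into every parameter. Training is bit-deterministic
for a fixed seed.

Inference binarises at 0.5 and keeps the largest 4-connected component;
an empty mask is legitimate output for a frame with no ventricle evidence.
A classical baseline (`baseline_segment()`: per-frame min-max
normalisation, Otsu or rank-quantile threshold, hole filling, largest
component) serves as a deterministic, model-free oracle on clean synthetic
data — on noiseless two-level frames it reproduces the rasterised ellipse
exactly — and as a fallback segmenter in the pipeline.

At the scale exercised by the tests (200 training frames of 64 x 64 px, 6
epochs, single CPU) the network reaches a pooled validation IoU of about
0.93; the suite asserts IoU >= 0.8 and a validation loss below its
first-epoch value. This shows the architecture trains and generalises on
easy synthetic data; it says nothing about performance on real microscope
images, which would require the original labelled dataset.

Overlap metrics (`seg_metrics()`) pool confusion counts over frames by
default (per-frame averaging is exposed); `DC = 2 IoU / (1 + IoU)` holds
identically under pooling, and the degenerate empty-vs-empty case scores 1
in all four metrics, vacuous precision/recall included.

## From masks to cardiac parameters

`area_trace()` counts foreground pixels per frame. `detect_cycles()` smooths
the trace with a centred moving average (window `max(3, fps/20)` frames, so
3 frames at 50 FPS), extracts alternating maxima/minima, and prunes
alternations whose amplitude is below 5% of the trace dynamic range —
ripple tolerance without losing genuine beats. Two boundary rules matter
and are deliberate:

* an endpoint **maximum** may serve as end-diastole (a video can begin or
  end at full relaxation — the simulator's first frame is one);
* a minimum at the **final sample** is an unfinished systole and never
  counts as end-systole, so a trailing partial contraction does not
  inflate the cycle count.

Each smoothed extremum is then refined to the raw-trace extremum within its
own smoothing window; the refinement is local by construction so a
marginally taller neighbouring peak cannot capture it. A complete cycle is
an end-diastole followed by its end-systole; `HR` is the complete-cycle
count over the video duration, times 60. For a 2-s video this quantises HR
to multiples of 30 bpm — the price of the counting definition on short
videos, shared by manual counting.

Cycle-wise EDA/ESA and rectangle axes are averaged across cycles by default
(`ed_es_mode = "mean"`); the single global extremum variant is exposed, as
either reading is defensible and the automated path in the source protocol
is not specified. Cycles where ESA exceeds EDA are rejected with a warning.

`min_area_rect()` implements the rotated minimum-area enclosing rectangle
with pixels as unit squares (a lone pixel measures 1 x 1): convex hull of
boundary-pixel corners, then rotating calipers — the minimal rectangle has a
side collinear with a hull edge, so scanning hull edges is exact, which the
tests confirm against an exhaustive 0.5-degree rotation search. Note the
convention's geometric consequence: a rotated w x h rectangle rasterised and
re-measured can read up to `|cos| + |sin|` (at most ~1.37) px larger per
side, because corner squares of boundary pixels protrude; the tests assert
these convention-implied bounds.

### The stroke-volume axis convention

The SV formula above uses the rectangle sides directly. Its cited ancestry
is a prolate-spheroid volume, which requires *semi*-axes — all sides halved,
giving exactly 1/8 of the as-printed value. Both conventions are
implemented (`sv_convention = "as-printed"` or `"semi-axis"`); the default
follows the printed formula, and because the screen's rescue index is
invariant to any common rescaling of a parameter, the choice does not
affect screening results. It does affect absolute SV values, so the option
is surfaced rather than silently resolved.

## Heart-rate estimation

`build_hrnet()` maps a ventricular-area sequence to one non-negative
scalar (bpm) in three stages: a 3-layer 1-D CNN (kernels of width 5,
channels 8/16/16, length-halving max-pools after the first two layers); an
inception stage of parallel convolutions with kernels 3, 7 and 15 whose
outputs are concatenated — the multi-kernel widths cover beat periods from
fast (240 bpm, ~12 frames) to slow (60 bpm, 50 frames); and global average
pooling into a 3-layer MLP (32/16/1) with a softplus output enforcing
non-negativity (final bias initialised at 100 so the untrained network
starts mid-range). Input traces are linearly resampled to 100 samples and
standardised to zero mean, unit variance (a constant trace maps to zeros);
resampling rather than cropping keeps the cycles-per-sequence content of
traces of other lengths.

Training minimises mean squared error on bpm (Adam, learning rate 3e-3, 60
epochs, batch 32) over simulator traces with randomised amplitude, baseline,
phase, waveform asymmetry and noise, so the only reliable signal is the
periodicity itself. On 500 traces spanning 60-240 bpm with a 4:1 split the
validation MAE is about 1-2 bpm with Pearson r > 0.99; the suite asserts
MAE <= 10 and r >= 0.9. The peak-counting oracle (`hr_peak_oracle()`:
cycle detection plus the counting formula) is exact on clean traces and
bounds what the network should achieve there; the network's value is
graceful degradation on noisy traces and freedom from the 30-bpm
quantisation of counting on 2-s videos.

`hr_metrics()` reports RMSE, MAE, Pearson r and the **population** standard
deviation of signed errors, so `rmse^2 = mean_error^2 + sd^2` holds exactly
(the reference metric set names "SD" without defining it; the population
form makes the decomposition an identity). Zero-variance inputs yield an
undefined correlation reported as `NA`, never silently 0.

## Phenotypic screening

A screen compares each compound group against a healthy control group and
an untreated disease-model group. For each parameter X the **rescue index**
is

\[ \mathrm{RI} = \frac{X_{drug} - X_{model}}{X_{ctrl} - X_{model}}, \]

computed on group means (per-larva mode is exposed for sensitivity
analysis): 0 = no improvement over the model, 1 = full restoration.
Pericardial edema enters as a seventh parameter with equal weight, coded
per larva as normal = 1 / edema = 0 and averaged to the fraction of normal
larvae. The **efficacy score** is the mean rescue index over usable
parameters; a degenerate parameter (control mean equal to model mean) is
excluded from numerator and denominator with a warning rather than
zero-filled. Indices are *not* clamped by default — worsening (< 0) and
over-rescue (> 1) remain visible; `clamp = TRUE` truncates to [0, 1].
Hits are scores **strictly** above the threshold (default 0.7), and ranking
is by descending score with lexicographic tie-breaking on compound id.

The score inherits two useful invariances, both tested: it is unchanged by
any common affine rescaling of a parameter across the three groups (so
pixel vs physical units, or the SV convention, cannot matter), and by
permutation of parameter or larva order.

`simulate_screen()` builds a complete in-silico screen: a control condition
(150 bpm, 30% axis contraction), a disease model (90 bpm, 12% contraction,
15% smaller ventricle, edema), and compound groups whose dynamics
interpolate between them by a rescue level in [0, 1]. A level-1 compound
reuses the control group's exact specifications and seeds (and level 0 the
model's), so full rescue scores exactly 1 and a null compound exactly 0 —
an end-to-end identity check through simulation, segmentation, parameter
extraction and scoring. Inter-larva variability is confined to nuisance
parameters (orientation, position, imaging noise) plus a +-3% ventricle
size scale: the graded series differs in 0.25-level steps estimated from
means of 5 larvae, and the screen is designed so the injected signal
dominates the group-mean sampling noise — the property under test is the
scoring layer, not the statistical power of minimal-n screens. With larger
per-larva geometry variation the EDA/ESA/SV indices at n = 5 become noise-
dominated, which is worth remembering when interpreting real screens of
this size.

## Numerical and interface conventions

* Images are H x W matrices in (row, col) coordinates; frame indices are
  1-based throughout the R API (the language's convention); pixels are unit
  squares centred on integer coordinates.
* Intensities live in [0, 1] in memory; videos export as 16-bit multi-page
  TIFF with a JSON frame-rate sidecar, masks as 8-bit 0/255 PNGs.
* CSV outputs have fixed column order and floats at 6 significant digits,
  written byte-deterministically; rerunning any stage with the same seed
  reproduces files byte for byte.
* All randomness (weight initialisation, shuffling, splits, simulation
  noise) flows from explicit integer seeds through an RNG-state-preserving
  scope, so library calls never perturb a caller's RNG stream.
* Ties: the largest connected component breaks ties by lowest label;
  compound ranking breaks score ties lexicographically; `axis_pair` swaps
  sides so `a >= b` always.

## Scale of the shipped experiments

The test-suite and acceptance-script problem sizes — 250 labelled frames of
64 x 64 px with 6 training epochs for segmentation, 500 traces for
heart-rate training, 4 noiseless recovery videos, a 7-group screen of 5
larvae each — are chosen so the full suite completes in minutes on one CPU
while still exercising every code path at meaningful accuracy. The
dataset-protocol arithmetic (2125 frames splitting 1700/425 at 4:1,
expansion by 3 to 5100) is tested at full size, since it is cheap.

## Known limitations

* Synthetic-only validation: no claim transfers to real microscope images
  without retraining and re-evaluation on labelled real data.
* HR from cycle counting is quantised to 30-bpm steps on 2-s videos; the
  network estimator avoids this but inherits the simulator's waveform
  family.
* The segmentation network is single-class (ventricle); atrium analysis and
  3-D reconstruction are out of scope.
* Minimum-area rectangles on very small or single-pixel masks are dominated
  by the unit-square convention; axes below ~8 px carry >3% rasterisation
  error.
* The CPU training engine is adequate for the shipped problem sizes, not
  for full-scale training; the architecture code is the reference, not a
  performance claim.
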