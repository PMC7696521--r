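---
title: "Hemispheric asymmetry images and convolutional classification of EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemispheric asymmetry images and convolutional classification of EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the representation

Hemispheric asymmetry of EEG band power — particularly alpha-band (8–13 Hz)
asymmetry between homologous left/right electrodes — is one of the more
robust electrophysiological correlates of major depressive disorder (MDD).
`deepasym` operationalizes this observation as a *signal-to-image* pipeline:
instead of feeding a classifier hand-picked scalar features, every 4-second
EEG epoch is converted into a 16×16 matrix of pairwise asymmetry scores,
rendered as a small RGB image, and classified by a compact convolutional
network that learns which spatial patterns of asymmetry separate MDD-like
from control-like recordings.

For channels $ch_1, ch_2$ with relative band powers $Rp_{ch_1}, Rp_{ch_2}$,
the asymmetry score is the normalized difference

$$A(ch_1, ch_2) = \frac{Rp_{ch_1} - Rp_{ch_2}}{Rp_{ch_1} + Rp_{ch_2}} \in [-1, 1],$$

where the relative power of a channel is the ratio of its Simpson-integrated
Welch power spectral density over the analysis band $[f_1, f_2]$ to the
integral over the total 0.5–30 Hz range. $A$ is antisymmetric
($A(a,b) = -A(b,a)$), zero between channels of equal relative power, and —
because relative power is a ratio — invariant to any per-channel positive
amplitude rescaling. The 16 channels are ordered left hemisphere first
(Fp1, F3, C3, P3, O1, F7, T3, T5) then their right homologs
(Fp2, F4, C4, P4, O2, F8, T4, T6); midline electrodes carry no lateral
information and are excluded.

## Preprocessing

Recordings are read from EDF (a hand-written reader/writer is included, as
EDF is a simple fixed-layout 16-bit format; channel-label matching tolerates
vendor decorations such as `"EEG Fp1-LE"`). The pipeline is

1. `minmax_normalize()` — each channel mapped to $[0,1]$ over the whole
   recording. The scope (whole recording, not per epoch) avoids epoch-to-
   epoch scale jitter; because relative power is scale-invariant this step
   cannot change the downstream features, which the test suite asserts.
2. `apply_ica_hook()` — artifact removal is a pluggable stage. Automatic
   component selection is operator- and dataset-specific, so no ICA
   rejection rule is shipped; any function preserving the recording's shape
   can be supplied, and the default is the identity. Normalization is
   applied before the hook, and the order is fixed and documented.
3. `segment_epochs()` — consecutive non-overlapping 4 s epochs (1024
   samples at 256 Hz) from time zero; a trailing partial segment is
   discarded because the classifier consumes fixed-size inputs.
4. `bandpass_notch()` — optional 0.5–70 Hz band-pass with a 50 Hz notch
   (zero-phase Butterworth), off by default since typical source data
   arrive acquisition-filtered.

## Spectral estimation and the window rule

`welch_psd()` averages periodograms of Hann-tapered, mean-detrended
segments with 50 % overlap. The segment length follows the rule *window
duration = 2 / (lower frequency of interest)*, capped at the epoch length.
Two readings of "lower frequency of interest" are supported:

* `window_rule = "band"` — the analysis band's own $f_1$ (alpha: $2/8 =
  0.25$ s, 64 samples), guaranteeing at least two cycles of the slowest
  in-band component per segment;
* `window_rule = "total"` — the 0.5 Hz lower edge of the denominator
  range, giving a 4 s window, i.e. a single full-epoch taper.

`relative_power()` defaults to `"total"`. The reason is numerical: both
integrals of the ratio are evaluated on one shared frequency grid, and the
band reading leaves the 5 Hz-wide alpha band with only two grid points at
its 4 Hz resolution. On such a coarse grid no quadrature can simultaneously
localize a narrowband oscillation inside its band and reproduce the flat-
spectrum expectation $Rp \approx (f_2-f_1)/29.5$ — the quadrature weights
required by the two cases contradict each other. With the 4 s window
(0.25 Hz grid) both hold: a pure 10 Hz tone yields alpha $Rp \ge 0.95$ and
white noise averages $5/29.5 \approx 0.169$. The per-band reading remains
selectable for users who want the coarser, variance-reducing estimate.

`band_power()` integrates the PSD over the grid frequencies inside the
closed interval $[f_1, f_2]$ with the composite Simpson rule (trapezoid
correction on an even point count, trapezoid fallback with a warning below
three points). Closed intervals mean shared band edges (8 Hz belongs to
both theta and alpha); the induced bias is shared by numerator and
denominator. Hann taper and constant detrending are the conventional Welch
defaults and are recorded in the spectrum object.

## Imaging

`colorize()` maps scores through a fixed piecewise-linear jet-style
diverging lookup — $-1$ at the blue endpoint, 0 in the green midrange, $+1$
at the red endpoint — with **no per-image autoscaling**, so one color means
one asymmetry value across the whole dataset, and the map is injective.
`upscale()` expands the 16×16 grid to the 64×64×3 classifier input by
nearest-neighbor block replication. Replication (rather than plot
rasterization or smooth interpolation) preserves the cell semantics of the
matrix, introduces no colors absent from the data, and is exactly
invertible from block centers. No axes, margins or color bars are rendered
into the tensor: decoration pixels are constant across classes and would
waste network capacity. Images are exchanged as 8-bit RGB PNG; in memory
components stay floating point in $[0,1]$.

## The classifier

`build_cnn()`/`train_cnn()` implement a three-block CNN in compiled code
(single-precision im2col + GEMM convolutions):

| block | layers | output |
|---|---|---|
| 1 | Conv 32@3×3 (valid, stride 1) + ReLU → MaxPool 2×2 → BatchNorm | 31×31×32 |
| 2 | Conv 64@3×3 + ReLU → MaxPool | 14×14×64 |
| 3 | Conv 128@3×3 + ReLU → MaxPool | 6×6×128 |
| head | Flatten 4608 → Dense 256 + ReLU → Dropout → Dense 1 + sigmoid | 1 |

Valid padding and floor-division pooling are forced by the layer shapes
(64→62, 29→14). The parameter count per convolution is
$(k^2 c_{in}+1)c_{out}$; batch normalization stores scale, shift, moving
mean and moving variance (128 values for 32 channels, the moving pair
non-trainable), for 1,273,537 parameters in total.

Training: Adam (learning rate $10^{-4}$, $\beta_1 = 0.9$, $\beta_2 =
0.999$, $\epsilon = 10^{-7}$) on binary cross-entropy for 10 epochs of
mini-batches of 32. Where the architecture leaves choices open, the
conventional companions were adopted and recorded in the configuration:
ReLU on the hidden dense layer, dropout rate 0.5, Glorot-uniform weight
initialization, batch-norm momentum 0.99 with $\epsilon = 10^{-3}$. The
moving batch-norm statistics are seeded from the first training batch and
momentum-updated afterwards, so inference is well-calibrated even after
short trainings. One integer seed drives weight initialization, epoch
shuffling and dropout masks through R's RNG: identical seeds give
bit-identical models on the same numerical backend (across BLAS builds
only statistical reproducibility is promised). MDD is the positive class
(label 1), so sensitivity is the true-positive rate over patients.

## Evaluation

`cross_validate()` performs $k$-fold (default 5) cross-validation:
shuffled near-equal folds, one fold held out per round, fresh model per
round (fold $f$ trains under seed $s + f - 1$). Two split modes:

* **epoch-level** (default): individual epochs are shuffled irrespective of
  subject. This matches the common practice of randomly mixing segmented
  data, but lets epochs of one subject appear on both sides of a split —
  every report carries an explicit leakage note.
* **subject-level**: whole subjects are held out; the honest estimate of
  generalization to new individuals.

Folds are unstratified by default (plain random mixing); stratified splits
are available by flag. Accuracy, sensitivity and specificity come from the
0.5-threshold confusion matrix; accuracy uses the standard
$(TP+TN)/(TP+TN+FP+FN)$ denominator. ROC curves sweep all distinct score
thresholds and AUC is the trapezoid integral, which equals the Mann–Whitney
pair-ordering statistic with half credit for ties (asserted against
exhaustive pair counting and against pROC in the tests). The mean ROC over
folds is obtained by vertical averaging of TPR on a fixed 101-point FPR
grid.

## The synthetic generator

Real MDD/control EEG cannot be bundled, so `synth_spec()` /
`make_benchmark()` generate the study conditions: 16 channels, 256 Hz,
300 s per subject (75 epochs), 5 + 5 subjects per group by default. Each
channel is a sum of band-limited Gaussian noise in the four canonical bands
plus a pink ($1/f$) broadband floor. Band components are white noise
spectrally confined to the band (Fourier masking) and scaled to a target
RMS; band noise rather than pure sinusoids keeps the PSD spread across each
band, and the pink floor makes the relative-power denominator realistic.
Default RMS amplitudes (arbitrary microvolt-like units) are delta 20,
theta 10, alpha 20, beta 8, pink floor 10 — an eyes-closed-like,
alpha-dominant profile. The group effect multiplies the *alpha* amplitude
of the eight left-hemisphere channels of MDD-like subjects by
`asymmetry_effect` (1 = no effect), because alpha asymmetry is the band
this representation targets. Every subject's signal is a deterministic
function of `(seed, subject_id, group)`, so datasets extend without
regenerating existing subjects.

What the generator does **not** emulate: eye-blink/EMG artifacts, volume
conduction and inter-channel correlation, non-stationarity across a
session, individual alpha-peak variability, and medication effects.
Passing the synthetic benchmark therefore demonstrates that the pipeline
can recover a known lateralized alpha effect end-to-end — not that any
particular accuracy will transfer to clinical recordings.

## Problem sizes and numerical choices

The bundled benchmark uses 5 + 5 subjects × 75 epochs = 750 images with
`asymmetry_effect = 3` and 5-fold epoch-level cross-validation; the
label-permutation null reuses the same images with shuffled labels. Unit
tests exercise the generator at 5–60 s durations, where relative-power
statistics are already stable. Degenerate inputs are errors, not silent
results: constant channels in min-max normalization, zero total power in
relative power, `rp1 + rp2 = 0` in the asymmetry score, single-class
training sets, and single-class ROC all raise or mark explicitly. The
Simpson integrator falls back to the trapezoid rule (with a warning) when
a band holds fewer than three grid points.

## Known limitations

* Epoch-level cross-validation overstates subject-level generalization;
  use `mode = "subject"` for deployment-relevant numbers.
* The CNN is specialized to the 64×64×3 input and the fixed 16-channel
  montage; other montages require retraining and a different channel
  order.
* One asymmetry image is produced per epoch; averaging matrices across
  epochs before imaging is a reasonable alternative this package does not
  implement.
* EDF support covers uniform-rate, single-record-duration files — the
  common case for resting-state exports; EDF+ annotations are ignored.
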