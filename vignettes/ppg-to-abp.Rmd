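---
title: "Estimating continuous arterial pressure waveforms from PPG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating continuous arterial pressure waveforms from PPG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgabp)
```

## The problem

Continuous arterial blood pressure (ABP) is normally measured invasively or
with a bulky cuff-based monitor, while the photoplethysmogram (PPG) — the
optical pulse signal behind every fingertip oximeter and smartwatch — is
cheap and ubiquitous. Because both signals are driven by the same cardiac
ejection, the PPG carries information about the pressure waveform. `ppgabp`
implements a signal-to-signal translation approach: 1D convolutional
autoencoders map each 5-second, 640-sample PPG window (128 Hz) to the
aligned 640-sample ABP window in mmHg. Systolic pressure (SBP) is then read
off as the maximum of a predicted 5-s window and diastolic pressure (DBP) as
its minimum, on the grounds that pressure does not change appreciably within
five seconds.

## The synthetic generator

No public paired PPG/ABP dataset ships with the package, so the pipeline is
exercised on synthetic records from `generate_record()` /
`generate_cohort()`. Each record is a train of beats whose inter-beat
intervals are drawn from a truncated normal (mean `60/hr_mean`, SD scaled by
`hr_sd`, floored at 30% of the mean). Every beat contributes a two-Gaussian
pulse — a primary systolic peak plus a smaller dicrotic bump — to both
channels. This is the simplest shape family that exhibits the "strong or
weak secondary peak" morphology the models must cope with in real pulses.

The ABP pulse is min–max anchored per beat so that its samples span exactly
`[DBP_t, SBP_t]`; the per-beat targets follow a slow sinusoid of amplitude
`drift_amplitude` (mmHg) around the configured bases, with DBP drifting at
half amplitude so pulse pressure stays positive. The PPG channel uses a
related template with shifted peak positions and widths, a baseline
proportional to DBP and an amplitude proportional to pulse pressure. The
PPG→ABP map is therefore deterministic and learnable: with zero noise a
sufficiently trained network can in principle recover the ABP window
exactly, which is the basis of the parameter-recovery checks below.

Defaults are conventional adult resting values — 75 ± 3 bpm, 120/80 mmHg
bases, ±10 mmHg drift over 60 s, and uniform ±10% subject-level jitter on
heart rate and pressure bases in cohorts. The artifact model corrupts a
contiguous block of 5-s windows (a configurable fraction) with either a
flatline or broadband noise, standing in for electrosurgical interference
and probe handling, which cannot be simulated literally.

What the generator does **not** emulate: true hemodynamics (no Windkessel
calibration, no pulse-transit-time physics), motion artifacts with realistic
spectra, sensor drift, arrhythmias, or the patient-to-patient morphological
diversity of real PPG. A model that passes the synthetic recovery tests has
demonstrated that the architecture, training loop and ensemble machinery
work; it has *not* been validated for clinical use.

## Preprocessing

`segment_windows()` cuts non-overlapping 5-s windows (640 samples at 128 Hz)
and drops any trailing remainder. Two filters assign per-window quality
flags:

* `range_filter()` rejects windows with any ABP sample outside
  [10, 250] mmHg;
* `quality_filter()` is a reproducible surrogate for by-eye quality
  screening: it rejects flatline ABP or PPG (variance below `var_eps`) and
  implausible pulse pressure (window max − min outside [5, 150] mmHg).
  Thresholds are arguments, not constants.

Range rejection takes precedence over quality rejection, which makes flag
assignment independent of filter order. `split_windows()` partitions clean
windows at the *window* level (the protocol splits sequences, not patients)
into `floor(n × 0.85)` training and the remaining test windows; the test set
is frozen for everything downstream. PPG inputs are min–max scaled to [0, 1]
using training-set statistics only; ABP targets stay in mmHg so predictions
are directly interpretable.

## The two autoencoders

Both families use same-padded 1D convolutions with ReLU hidden activations
(`f(x) = max(0, x)`), factor-2 max pooling down the encoder and factor-2
nearest-neighbour upsampling back up, and a single-filter linear output
convolution.

* **LDCAE** (LeNet-5-style): filter ladder 16 → 32 → 64, no skip
  connections, kernel width 11. Realized size: 56,833 parameters.
* **UDCAE** (U-Net-style): ladder 32 → 64 → 128 → 256; the decoder
  concatenates each encoder level's feature map before convolving; kernel
  width 3. Realized size: 323,457 parameters.

Kernel widths and level counts are design choices made here: the reference
descriptions pin only the filter ladders and approximate parameter totals
("about sixty thousand" and "about three hundred thousand"), so kernels were
chosen to land inside those bands, and `count_params()` documents the exact
realized counts. A linear output head was preferred over ReLU to avoid
dead-output pathology at initialization; nearest-neighbour upsampling plus
convolution was preferred over transposed convolution for its freedom from
checkerboard artifacts.

## Training

`train_model()` runs mini-batch Adam (defaults 200 epochs, batch 16,
learning rate 1e-3, β₁ = 0.9, β₂ = 0.999, ε = 1e-7) on the mean squared
reconstruction error, with the training order reshuffled each epoch.
Internally the ABP targets are standardized (the inverse affine map is
stored on the model), which lets the optimizer reach the ~100 mmHg operating
point quickly without an enormous bias burn-in; reported losses are
converted back to mmHg². Ten percent of the training windows are held out as
a validation carve and the checkpoint with the lowest validation loss is
kept — the frozen test set is never consulted during training or checkpoint
selection. All randomness (weight draw, validation carve, shuffling) derives
from the configured seeds, so runs are bit-reproducible on a fixed BLAS.

## Cross-validation and model selection

`run_cv()` implements leave-testing-out cross-validation: one frozen test
set is shared by all folds, and only the training side is re-randomized per
fold. "Re-randomized" is read here as: each fold gets its own derived seed
governing weight initialization, the validation carve and the shuffle order,
while training-set *membership* is fixed. `summarize_cv()` reproduces the
familiar summary layout — per-fold correlation and error columns, column
means and sample (n−1) SDs, and a per-fold row average over all six
correlations (SBP/DBP/waveform × both families). The n−1 convention is
pinned by the published summary arithmetic, which matches the sample SD and
not the population SD. `select_best()` picks the fold with the highest row
average; although the selection is described elsewhere as an "average of SBP
and DBP", the printed value 0.9643 is reproducible only as the six-value row
mean, so that is what is implemented. Ties break toward the lower fold id.

## The genetic ensemble

`evolve_ga()` searches over binary chromosomes with one bit per candidate
cross-validation model (20 at full scale). A set bit includes that model in
an equally weighted ensemble whose prediction is the element-wise mean of
member waveforms; SBP/DBP are extracted from the *averaged* waveform, not
averaged per member — consistent with reporting waveform errors for the
ensemble. Fitness is `(r_SBP + r_DBP) / 2` against the reference.

Underspecified GA details were resolved as follows: "95% mutation rate" is
read as a per-offspring probability that exactly one uniformly chosen bit
flips (a 0.95 per-bit rate would randomize the search); selection is
tournament of size 2; elitism carries the single best chromosome, making
best-ever fitness non-decreasing; population size defaults to 32 (from the
reference's chromosome-size sweep); the all-zero chromosome is assigned
fitness −1 rather than repaired, keeping the search space intact. Candidate
predictions are precomputed once (`fitness_input()`), so fitness evaluation
never re-runs a model. `exhaustive_best()` enumerates all nonempty subsets
(refusing beyond 25 candidates) and serves as the independent oracle for the
search. Fitness is evaluated on the frozen test set, matching the apparent
full-scale protocol; note this is optimistically biased — selecting on the
same set you report on — and a validation-set alternative is simply a matter
of passing different windows to `fitness_input()`.

## Metric conventions

`pearson_r()` is the standard product-moment coefficient in [−1, 1] (the
reference text asserts [0, 1]; the standard definition is implemented and
the discrepancy noted rather than silently "corrected"). Waveform metrics
are pooled over all samples of all test windows rather than averaged per
window. Bland–Altman differences are estimate − reference (the sign is
flippable), with sample-SD limits at ±1.96 SD. Degenerate inputs fail
loudly: empty series, length mismatches and zero-variance correlations are
errors, as is a degenerate (max = min) normalizer.

## Scale of the shipped experiments

The package's tests and the acceptance script run the full pipeline at a
reduced reference scale chosen to be convincing while staying desk-sized:
4 synthetic subjects × 150 s (120 windows, 102 train / 18 test), noise-free
for parameter recovery, k = 2 folds per family at 30 epochs, and the
default GA (population 32, 2000 generations). At this scale the held-out
UDCAE waveform correlation exceeds 0.99 and the evolved ensemble at least
matches the best single model. The genetic-vs-exhaustive agreement check
uses 10 synthetic candidate prediction tables (1,023 subsets). Full-scale
settings (18 subjects, k = 10, 200 epochs) are plain configuration changes.

## Known limitations

* Synthetic validation only; no claim of clinical accuracy transfers to
  real patients.
* The quality filter is a heuristic stand-in for expert screening and will
  not catch subtle morphological corruption.
* Window-level splitting allows windows from one subject on both sides of
  the split; use subject-level assembly of window sets when leakage matters.
* SBP/DBP as window max/min ignores beat-to-beat variability within the
  window and is sensitive to residual spikes in predicted waveforms.
* Training determinism holds for a fixed BLAS/thread configuration.
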