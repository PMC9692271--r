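---
title: "Stress-state classification from heart rate variability: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-state classification from heart rate variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science implemented by `hrvstress`: the
signal-processing and feature model, the recurrent classifier, what the
synthetic cohort generator does and does not emulate, and the numerical and
design decisions a user should know before trusting or modifying results.

## 1. Problem and pipeline

Psychological stress modulates the autonomic nervous system, and that
modulation is visible in the beat-to-beat variation of the heart rhythm.
The package classifies four experimental stress states — resting, VR scene
adaptation, VR high-altitude task, and recovery (class labels 1, 4, 2, 3
respectively) — from ECG, in five stages: bandpass filtering and R-wave
detection; seven-feature HRV extraction per 30-s window; assembly of 20
overlapping windows into one 20×7 time-series sample per subject-state;
per-cell min–max standardization learned on training subjects; and a
cascaded stacked-GRU classifier evaluated cross-subject.

The unit of classification is one subject in one state: a 70-s RR record
becomes exactly one sample. A cohort of S subjects therefore yields 4·S
samples, balanced over the four classes by construction, which is why plain
accuracy (the per-class-correct count over the total) is the headline
metric and confusion matrices are row-normalized.

## 2. Preprocessing

The ECG is filtered with a fourth-order Butterworth bandpass, 10–35 Hz,
applied forward–backward so that filtering is zero-phase and R-peak
locations are not lag-shifted. Odd-symmetric reflection padding (one second
at each end) suppresses the edge transients of the forward–backward pass.
The passband keeps the sharp R wave while rejecting baseline wander and
movement artifact below 10 Hz and high-frequency noise above 35 Hz.

No specific R-detector is prescribed by the pipeline's design, so the
package uses a Pan–Tompkins-style chain — squaring, 150 ms moving-window
integration, adaptive signal/noise peak thresholds, 250 ms refractory
period — chosen because it is standard, robust and parameter-light at
250 Hz. Accepted events are refined to the local maximum of the filtered
waveform within ±100 ms, which localizes symmetric QRS complexes to the
sample. Detection runs on a single configurable lead (default lead 1);
multi-lead fusion is out of scope.

RR intervals outside [0.3, 2.0] s are treated as artifacts and dropped; if
more than 10% of a record's intervals are dropped the record is flagged low
quality (but not auto-excluded — exclusion criteria belong to the study
protocol, not the toolbox).

## 3. The seven HRV features

Each 30-s window of RR intervals is summarized by, in fixed order:

| Feature | Meaning | Convention used here |
|---|---|---|
| mRR | mean RR interval (s) | arithmetic mean |
| SDNN | SD of RR intervals (s) | population SD (divide by n) |
| HFn | normalized 0.15–0.4 Hz power | HF/(LF+HF) |
| LFn | normalized 0.04–0.15 Hz power | LF/(LF+HF) |
| LF/HF | sympathovagal balance index | ratio of band powers |
| ApEn | approximate entropy (nats) | m = 2, r = 0.2·SD, self-matches included |
| SD1/SD2 | Poincaré axis ratio | ratio of standard deviations |

Notes on the choices:

* **Spectral estimator.** Band powers come from the classic Lomb–Scargle
  periodogram evaluated directly on the irregular (beat time, RR) pairs, on
  a fixed grid 0.04–0.40 Hz with 0.002 Hz step, integrated by the trapezoid
  rule per band (the 0.15 Hz ordinate is shared by both bands). Lomb–Scargle
  avoids the interpolation artifacts that tachogram resampling introduces on
  windows this short. A caveat inherent to the design: a 30-s window holds
  only ~1.2 cycles at 0.04 Hz, so the LF estimate is noisy at the window
  length the pipeline prescribes; it is computed as specified.
* **Normalization.** "Normalized" LF/HF power is taken as a fraction of
  LF+HF — the common HRV convention that makes LFn + HFn = 1. Normalizing by
  total power instead would change LFn/HFn but not LF/HF.
* **ApEn.** Pincus defaults (m = 2, r = 0.2·SD of the window, Chebyshev
  distance, self-matches included), so ApEn ≥ 0 and a constant window gives
  exactly 0.
* **SD1/SD2.** The Poincaré cloud's dispersions along the −45° and +45°
  axes are computed as `sd((RRₖ₊₁−RRₖ)/√2)` and `sd((RRₖ₊₁+RRₖ)/√2)`.
  Descriptions of the plot sometimes say "variance along the axis", but the
  reported ratio is conventionally of standard deviations; the package
  returns the SD ratio and offers `variance_ratio = TRUE` (the square) for
  the other reading.
* **Degenerate windows.** Zero-variance windows are imputed neutrally
  (band powers 0, hence LFn = HFn = 0.5 and LF/HF = 1; ApEn 0; SD1/SD2 0;
  LF/HF capped at 100 when HF = 0) so the pipeline never emits non-finite
  features. A perfectly alternating RR series has SD2 = 0 and is rejected
  as degenerate by `poincare_ratio()` itself; `feature_vector()` only
  imputes the truly constant case.

All four nontrivial features are verified in the test suite against
independent brute-force oracles (exhaustive template counting for ApEn,
explicit 45° rotation for SD1/SD2, per-frequency scalar Lomb sums for the
band powers) to 1e-10.

## 4. Samples and standardization

Window i (i = 1…N) covers `[(i−1)·d, (i−1)·d + L)` seconds from the
record's first beat; an interval belongs to the window containing its later
beat. Defaults L = 30 s, d = 2 s, N = 20 require 68 s of record, which a
70-s state record satisfies; beats after 68 s can never influence the
sample, and windows with fewer than 8 intervals reject the record as too
sparse.

Standardization is per cell: for timestep i and feature j, the min and max
of that cell over the M training samples define a linear map
`(f − min)/(max − min)`. Training cells therefore land in [0, 1] with both
endpoints attained; validation/test samples reuse the training statistics
unchanged and are deliberately **not clipped** — out-of-range values carry
real cross-subject shift information. Cells with max = min map to 0 so that
degenerate synthetic configurations stay runnable.

## 5. The classifier

Each GRU cell follows the standard gate equations (reset gate r, update
gate z, candidate c, new state h′ = (1−z)⊙c + z⊙h). Biases are part of each
affine map; hidden states start at zero; weights initialize uniformly in
(−1/√H, 1/√H) per matrix (fan-in for the head), seeded for
reproducibility. A *block* stacks K layers, each layer consuming the
previous layer's per-step outputs; the model cascades two blocks, the
second reading the first's per-step outputs. The "multi-level deep feature"
is the concatenation of both blocks' last-step outputs (width 2H;
summation is the other reading of "composed of", but concatenation
preserves the levels separately and is what the head sizes imply). The head
is 64–32–4 with batch normalization then ReLU after each hidden layer and
softmax at the output.

The loss is cross entropy (softmax probabilities, ε = 1e-12 inside the
log) plus γ·‖W‖² summed over all GRU and fully connected weight matrices —
biases and batch-norm parameters are excluded, the conventional scope of L2
regularization. Batch normalization uses batch statistics during training;
for inference the statistics are re-estimated over the full training set at
the end of each epoch ("precise BN") rather than relying on the running
exponential average alone — in small-data regimes the momentum-0.9 average
lags the quickly moving activations enough to make inference inconsistent
with training. Inference is deterministic. Dropout is not used anywhere.

Training is Adam (β₁ = 0.9, β₂ = 0.999) over shuffled mini-batches for a
fixed number of epochs — no early stopping; the validation set is monitored
only, never used for model selection. A short final batch is kept (the loss
normalizes by the realized batch size). The full-scale defaults are
lr = 2·10⁻⁴, batch 52, 80 epochs, γ = 0.002, H = 256, K = 5.

The forward pass is verified against a scalar-loop implementation of the
gate equations, and the hand-derived backpropagation (through time, through
batch norm, and through the concatenated feature) is verified against
central finite differences on every parameter group.

## 6. The synthetic cohort generator

The study data this pipeline was designed for are private, so the package
generates RR records with an integral pulse frequency modulation (IPFM)
model: a beat fires whenever the integral of the instantaneous rate
`r(t) = (1 + m(t))/mean_rr` crosses an integer, with
`m(t) = lf·sin(2π·0.10·t+φ₁) + hf·sin(2π·0.25·t+φ₂) + ε(t)` and ε white
Gaussian rate noise. The carriers sit at the LF/HF band centers, which
gives direct, independent control over exactly the spectral features the
classifier consumes.

The four state templates (a package choice of plausible magnitudes — the
study reports no per-state physiology, only the qualitative stress ordering
resting < adaptation < recovery < task):

| state | label | mean RR (s) | lf_amp | hf_amp | noise_sd |
|---|---|---|---|---|---|
| resting | 1 | 0.85 | 0.03 | 0.09 | 0.02 |
| VR adaptation | 4 | 0.82 | 0.05 | 0.08 | 0.02 |
| recovery | 3 | 0.78 | 0.07 | 0.06 | 0.02 |
| VR task | 2 | 0.65 | 0.10 | 0.04 | 0.02 |

Mean heart rate rises and the LF:HF balance tilts toward LF as stress
grows. Inter-individual variation is modeled by three per-subject lognormal
factors — one on mean RR, one on lf_amp, one on hf_amp — fixed across a
subject's four states. Independent amplitude factors matter: they perturb
each subject's autonomic balance, so increasing `subject_jitter` genuinely
erodes the class signal a cross-subject split must generalize over. (A
single shared amplitude factor would leave every subject's LF:HF ratio
intact and jitter would barely hurt accuracy.)

Synthetic ECG, when needed for detector testing, is a unit-amplitude
Gaussian bump (σ = 12.5 ms, i.e. a ~50 ms R wave) at each beat time plus
white noise, with ground-truth beat times retained. The R-wave width is
deliberately sharp enough that its energy lies inside the 10–35 Hz
detection passband — the premise of that passband choice. An optional
`pad` argument prepends/appends baseline so no template is bisected by a
record edge, where single-sample localization is ill-posed.

What the generator does **not** emulate: PQRST morphology, respiratory
sinus arrhythmia as a coupled process, ectopy, non-stationarity within a
state, or any measured per-state physiology. Passing tests on synthetic
cohorts therefore demonstrate that the machinery is correct and that the
pipeline can recover class structure of the kind HRV theory predicts — not
that the classifier reaches any particular accuracy on real recordings.

## 7. Desk-scale experiment sizes

The test suite and the acceptance script run a reduced configuration:
24 subjects (18 training, of which 3 validation; 6 test), 2 blocks × 2
layers × 32 units, 30 epochs, 5 repeats — and lr 0.003 with batch 16. The
learning rate differs from the full-scale default deliberately: 30 epochs
on 72 training samples at batch 52 would give ~30 Adam updates, and at
lr 2·10⁻⁴ a fresh model cannot move measurably in 30 updates; the
reduced-scale recipe (≈135 updates at lr 0.003) is a stable, convergent
equivalent chosen by step-budget arithmetic. Each repeat re-draws the
subject split (re-splitting exercises cross-subject variance honestly;
re-initializing only the weights would understate it).

On this configuration the package's own runs give mean test accuracy 1.0
at zero jitter, degrading monotonically with jitter while staying well
above the 0.25 chance level — the numbers are recomputed, not quoted, by
`scripts/acceptance.R` and the acceptance tests.

## 8. Known limitations

* LF power on 30-s windows is intrinsically noisy (~1.2 LF cycles per
  window); the pipeline computes it as designed rather than lengthening the
  window.
* The R-peak detector is tuned for the synthetic template and clean-ish
  wearable ECG; it has no ectopy handling or lead fusion.
* Training the full-scale model (256 units × 10 GRU layers) in plain R is
  possible but slow; the package's R implementation targets the desk-scale
  configurations. The architecture sweeps (units ∈ {64, 128, 256, 512},
  layers ∈ {1, 3, 5, 7}, blocks ∈ {1, 2, 3}) are all expressible through
  `model_config()`.
* With four samples per batch-norm feature at the smallest batch sizes,
  batch statistics are noisy; batch sizes below ~8 are not recommended.
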