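# hrvstress

Classification of four psychological stress states — resting, VR scene
adaptation, VR (high-altitude) task, and recovery — from wearable-ECG heart
rate variability, using a cascaded stacked-GRU sequence model. The package is
aimed at researchers in physiological computing who want the full pipeline
(signal → features → time-series samples → recurrent classifier →
cross-subject evaluation) as inspectable, dependency-light R code, together
with a synthetic cohort generator so every stage can be exercised without
access to clinical recordings.

## The method

1. **Preprocessing.** Each ECG lead is filtered with a fourth-order
   zero-phase Butterworth bandpass (10–35 Hz); R waves are detected with a
   Pan–Tompkins-style chain (squaring, 150 ms moving-window integration,
   adaptive thresholding, 250 ms refractory period) and converted to RR
   intervals, with a physiologic artifact rule (RR ∈ [0.3, 2.0] s).
2. **HRV features.** For each RR window, seven features:
   mRR, SDNN (time domain); HFn, LFn, LF/HF from Lomb–Scargle band powers
   over 0.04–0.15 Hz (LF) and 0.15–0.4 Hz (HF); approximate entropy
   ApEn(m = 2, r = 0.2·SD); and the Poincaré ratio SD1/SD2.
3. **Sample construction.** A sliding window (length L = 30 s, step
   d = 2 s, N = 20 steps) turns each 70-s subject-state record into an
   N×7 matrix; each cell (i, j) is min–max standardized,
   f̂ᵢⱼ = (fᵢⱼ − min Fᵢⱼ)/(max Fᵢⱼ − min Fᵢⱼ), with the min/max taken over
   *training* samples only.
4. **Model.** Two cascaded GRU blocks (each K stacked layers of H units;
   full scale K = 5, H = 256) built from the gate equations
   r = σ(W_ir x + W_hr h), z = σ(W_iz x + W_hz h),
   c = tanh(W_ic x + W_hc (r⊙h)), h′ = (1−z)⊙c + z⊙h.
   The concatenated last-step outputs of both blocks feed a 64–32–4 fully
   connected head (batch norm + ReLU between layers) with a softmax output.
   Training minimizes cross entropy + γ‖W‖² with Adam
   (γ = 0.002, lr = 2·10⁻⁴, batch 52, 80 epochs at full scale).
5. **Evaluation.** Cross-subject splits (47 training subjects of which 8
   validation, 16 test at the 63-subject study scale), accuracy
   (T₁+T₂+T₃+T₄)/M, row-normalized 4×4 confusion matrices, and the mean over
   five repeated experiments.

Forward pass, backpropagation through time, batch normalization and Adam are
implemented in plain R matrix code and verified against scalar-loop oracles
and finite differences in the test suite.

## Worked example

Because the study's clinical recordings are private, the package ships an
IPFM (integral pulse frequency modulation) generator whose four state
templates differ in mean RR and LF/HF balance. A desk-scale experiment —
24 subjects, a reduced model (2 blocks × 2 layers × 32 units), 30 epochs —
runs in a few minutes on one CPU:

```r
library(hrvstress)

cohort  <- generate_cohort(cohort_config(n_subjects = 24,
                                         subject_jitter = 0.2, seed = 11))
samples <- build_cohort_samples(cohort)           # 96 samples of 20 x 7
mc <- model_config(n_blocks = 2, layers_per_block = 2, hidden_units = 32,
                   seq_len = 20)
tc <- train_config(lr = 0.003, batch_size = 16, epochs = 30, repeats = 5,
                   seed_base = 1)
res <- repeat_experiment(samples, mc, tc, n_train = 18, n_val = 3)
res$mean_accuracy
#> [1] 0.7666667
round(res$accuracies, 2)
#> [1] 0.75 0.83 0.71 0.79 0.75
res$reports[[1]]
#> <eval_report> accuracy 0.750 on 24 samples
#>     predicted
#> true    1    2    3    4
#>    1 0.67 0.00 0.00 0.33
#>    2 0.00 1.00 0.00 0.00
#>    3 0.00 0.17 0.83 0.00
#>    4 0.00 0.00 0.50 0.50
```

Each repeat re-draws the cross-subject split, re-fits the standardizer on
its training subjects, trains from a fresh initialization, and evaluates on
the held-out subjects; `mean_accuracy` is the average test accuracy over
repeats. With zero `subject_jitter` the four states are recovered
perfectly; at the strong jitter shown here accuracy degrades to ~0.77, and
the confusion concentrates between resting (class 1) and VR scene
adaptation (class 4) — the two physiologically closest states, whose
templates differ least in heart rate and LF/HF balance.

The same pipeline is scriptable from a shell via `inst/cli/hrvstress`
(`simulate`, `features`, `traineval` subcommands).

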