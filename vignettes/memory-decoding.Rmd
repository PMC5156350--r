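---
title: "Decoding subsequent memory from single-trial EEG: model and methods"
author: "conveegnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding subsequent memory from single-trial EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conveegnn)
```

## The problem

During a study phase, an auditory cue announces each spoken word 1.5 s in
advance; participants later judge each word's familiarity on a five-point
scale (keys 1–2 count the trial as *remembered*, keys 3–5 as *forgotten*).
The subsequent memory effect (SME) is the statistical difference between EEG
preceding and accompanying later-remembered versus later-forgotten events:
frontally, remembered trials show a more negative-going potential in the
cue–word interval and a more positive-going one during the word. The package
asks the single-trial question: given one trial's EEG, will this word be
remembered?

Formally, with `I` an `N_ch x T` matrix of one trial's channel-by-time
voltages and `Z` its later memory outcome, we learn `H : I -> Z` from
labeled trials.

## The network

The classifier is a five-layer convolutional network:

* **Input** `L_in`: the `N_ch x T` matrix, `N_ch = 30` channels (the
  montage minus the two EOG channels), `T = 75` for the entire epoch at
  25 Hz, or `T = 30` for the pre-/during-stimulus windows.
* **Spatial convolution** `L_c`: `N_c` feature maps; the kernel of map `m`
  spans all `M = N_ch` channels at a single time index and slides over time
  with stride 1, so each map is a learned channel combination evaluated at
  every time point (`S = T` outputs; `N_c (M + 1)` parameters). If the
  input shifts in time, the feature map shifts with it.
* **Temporal convolution + subsampling** `L_cs`: map `m` applies a kernel
  of length `K_m = T / P_m` with stride `K_m` (non-overlapping receptive
  fields), simultaneously filtering and downsampling to `P_m` outputs;
  `sum(K_m + 1)` parameters.
* **Hidden** `L_h`: `Q = 10` fully connected logistic neurons.
* **Output** `L_out`: two logistic neurons `(Z0, Z1)`; a trial is predicted
  *forgotten* iff `Z0 > Z1`, otherwise *remembered* (ties fall to
  remembered by the literal reading of the decision rule). The two output
  neurons are nominally the two classes in the order remembered/forgotten,
  but the operational decision rule above is what the package implements;
  the apparent naming inconsistency in the source description is resolved
  in favor of the operational rule.

Both convolutional layers use the scaled hyperbolic tangent
`f(u) = 1.7159 * tanh(2/3 * u)`. `countParams()` reproduces the closed-form
per-layer parameter and connection counts.

## Learning

Training minimizes the half squared error `E = 0.5 * ||Z - t||^2` with
one-hot targets (`(1,0)` = forgotten, `(0,1)` = remembered) by plain
per-sample stochastic gradient descent with epoch-wise reshuffling.
Weights of a neuron with `n` inputs are initialized uniformly on
`[-1/sqrt(n), +1/sqrt(n)]` ("standard distribution around ±1/sqrt(n)";
a Gaussian variant with SD `1/sqrt(n)` sits behind `init = "gaussian"`).
The labeled samples are split 70/30 into training and validation sets —
stratified, so small classes reach the validation set — and the minority
training class is duplicated cyclically until the classes balance. Training
stops when the validation MSE has not improved for `patience` epochs, and
the parameters at the validation minimum are returned.

Unstated hyperparameters were fixed once as: learning rate 0.01, at most
400 epochs, patience 25. On fold-sized training sets (~70 samples) this
loss surface is noticeably sensitive to the initialization, so a fit runs
`nRestarts = 5` independent initializations on the *same* split and keeps
the run with the lowest validation MSE; this uses training data only and
does not alter the per-run algorithm.

## Preprocessing

Six steps, in order, each stamping its provenance tag:

1. **Re-reference** to linked mastoids (subtract the TP9/TP10 mean from
   every non-EOG channel).
2. **Band-pass 0.05–15 Hz, zero phase.** Implemented spectrally: the FFT of
   each channel (even-reflection padded) is multiplied by the squared
   magnitude of a 4th-order Butterworth high-pass × 4th-order low-pass
   cascade — exactly the two-pass (forward–backward) magnitude response,
   ~48 dB/octave per edge, with identically zero phase. A time-domain
   8th-order band-pass with a 0.05 Hz edge at 500 Hz (normalized frequency
   2e-4) is numerically unstable in transfer-function form; the spectral
   realization is exact and makes zero-phase properties (impulse latency
   preservation, commutation with time reversal) hold to rounding error.
3. **EOG regression**: least-squares propagation factors of VEOG and HEOG,
   estimated on the whole continuous recording (before segmentation, per
   the step order), are subtracted from every EEG channel. Flat EOG
   channels are skipped with a warning.
4. **Segmentation** into `[-0.1, 2.9)` s epochs around each cue
   (half-open; sample index `= onset + round(t * rate)`); EOG channels are
   dropped here; labels attach from the response keys.
5. **Baseline correction** over `[-0.1, 0)` s, per trial and channel.
6. **Artifact rejection**: a trial is dropped iff any sample exceeds
   ±50 µV strictly (a peak exactly at 50 µV is retained — the threshold's
   boundary semantics are unstated, so the strict reading was fixed once),
   or the trial carries a movement annotation. Retained trials are
   untouched; the log records one reason per dropped trial.

**Input normalization.** Epochs are decimated 500 → 25 Hz through a
zero-phase anti-aliasing low-pass at 10 Hz (0.8 × the new Nyquist) before
picking every 20th sample; `naiveDecimate = TRUE` reproduces plain picking
for comparison, since the original description says only "subsampled".
The window is then cropped (entire `[-0.1, 2.9)` → T = 75; pre
`[0.3, 1.5)` and during `[1.5, 2.7)` → T = 30) and each channel is
z-normalized. Normalization scope is per channel, with statistics estimated
on the training trials of a fold and *echoed* — never recomputed — when
applied to held-out trials; whether the original analysis scoped statistics
this way is unstated, and this choice prevents test-set leakage.

## Evaluation protocol

Cross-validation is leave-pair-out: each test fold holds one random trial
of each class (without replacement), repeated until every trial has been
tested exactly once; with unequal classes the leftover majority trials are
tested in singleton folds — the closest satisfiable reading of "one sample
from each class, each used exactly once". Accuracy pools the held-out
predictions over all folds (equivalent to averaging per-fold accuracies
only when folds are equal-sized; pooling keeps singleton folds from
distorting the mean). Significance is the exact one-sided binomial tail
`P(X >= n_correct | n, 0.5)` at `p < 0.05`; per-participant `n` is small,
so no normal approximation is used.

Participant inclusion follows the published rules: fewer than 15
remembered or 15 forgotten words excludes (inclusive threshold), as does a
response bias above 0.2 (strict). The bias statistic itself is not spelled
out in the source; `responseBias()` implements the interpretation
`P(key in {1,2} | new word)` and is documented as such.

## Comparison classifiers

Six baselines share the fold plans, normalization discipline and seeds of
the network through one `fitClassifier()`/`predictClassifier()` contract:

* **LDA**: Fisher discriminant with ridge-stabilized pooled covariance
  (ridge relative to the mean diagonal, default 0.1); for `p > n` the
  solve uses the Woodbury identity in sample space.
* **ANN-1 / ANN-2**: fully connected nets (hidden 10, and 20–10), first
  hidden layer scaled tanh, later layers logistic, trained with the same
  SGD/early-stopping/balancing machinery as the convolutional network.
* **SVM**: soft-margin C-SVM with cubic polynomial kernel; the cost is
  chosen on an internal stratified validation split. (The earlier work
  this baseline descends from used a ν-SVM; the reimplementation here
  specifies only the cubic kernel, so the common C-form was chosen.)
* **SVM+LDA fusion**: per window (pre, during), CSP spatial filters (2
  top + 2 bottom eigenvectors of the whitened class-covariance problem)
  feed log-variance features into a cubic SVM; an LDA handles the
  downsampled during-window amplitudes; the three standardized decision
  values are averaged and thresholded at zero (majority vote behind
  `rule = "vote"`; the original fusion rule is unstated).
* **CWT+SVM**: Morlet wavelet (6 cycles) band power at 4.00, 6.42 and
  11.26 Hz — the theta-1, theta-2 and alpha centers compatible with the
  0.05–15 Hz band — averaged per window and per channel pool
  (frontal/central/posterior, mirroring the three scalp sites of the
  original design at this montage), classified by an L1-regularized
  logistic model (the "1-norm SVM" role; the penalty induces the same
  sparse linear weighting).

## The synthetic generator

`simulateSession()` emulates the study phase: 32-channel, 500 Hz
recordings; cue at 0 s, word at 1.5 s; epochs spanning `[-0.1, 2.9)` s
tiled with a 0.7 s gap (response pause + the fixed 0.6 s inter-stimulus
interval). Per trial it sums:

* `1/f^alpha` background noise (frequency-domain synthesis, `alpha = 1`)
  plus white noise — a reasonable match to resting EEG spectra;
* a class-neutral evoked template: Gaussian-windowed deflections for the
  cue and word responses with a frontally weighted topography (the source
  gives polarities and windows, not waveform equations);
* the class effect: for remembered trials only, −2 µV sustained over
  `[0.3, 1.5)` s and +2 µV over `[1.5, 2.7)` s on five frontal channels
  (Fp1, Fp2, F7, F8, F3), so the empirical window-mean class difference
  converges exactly to the configured amplitudes;
* a theta oscillation (5 Hz, random phase per trial) with a small
  remembered-class amplitude increment on the effect channels;
* blinks: a Poisson process mirrored on VEOG with a fixed
  frontal-to-posterior attenuation profile, so EOG regression is
  recoverable and testable; occasional horizontal saccades on HEOG;
* sub-threshold spatially coherent transients (random topography, 0.05 to
  0.15 s, capped at 32 µV): residual muscle/electrode artifacts that
  survive amplitude rejection, present in real recordings;
* drift: a slow ±100 µV ramp on `round(driftTrialFraction * nTrials)`
  trials, guaranteed to cross the rejection threshold.

Labels are Bernoulli(`pRemembered`); remembered trials emit keys 1–2,
forgotten 3–5, exercising the labeling path. `simulateEpochs()` emits the
equivalent clean, segmented, baseline-corrected trials directly for fast
tests.

**Calibration.** The effect amplitudes are free parameters (the source
reports no single-trial SNR), so the background level was calibrated once:
`noiseSigma = 9` µV puts leave-pair-out ridge-LDA on the entire window at
roughly 55–65% for 100 trials. All tests use these defaults unless a test
explicitly probes another regime.

**What the generator does not emulate — and what that implies.** The class
signal is an additive Gaussian mean shift. For such signals a regularized
linear discriminant is close to Bayes-optimal, so no classifier — including
the convolutional network — can beat it by a wide margin; at fold-sized
training sets (~70 trials) the network's stochastic optimization in fact
leaves it at or slightly below the LDA. Real EEG evidently contains
nonlinear or nonstationary memory-predictive structure that this generator
does not produce; synthetic absolute accuracies are therefore *not*
comparable to accuracies reported on recorded EEG, and the network's
documented advantage over linear baselines on real data should not be
expected to reproduce here. The test suite treats network-vs-LDA ordering
accordingly: properties that are about the protocol (fold exclusivity, no
leakage, null calibration), about calibration (window effects, polarities)
or about mechanism (gradient correctness, oracle equivalence, shift
covariance, channel recovery) are asserted; the absolute synthetic-accuracy
regime is reported as measured.

## Numerical choices and degenerate inputs

* Time convention: cue onset = 0 s; all windows half-open `[t0, t1)`;
  sample index `round((t - t_start) * rate)`.
* The zero-phase filter pads by even reflection to a length with small
  prime factors (fast FFT) and equal left/right pads, which makes
  filtering commute with time reversal exactly.
* `windowIndices()` errors on empty windows; `prepareInput()` errors if a
  window bound is not sample-aligned at the target rate.
* Ties in `topChannels()` break by montage order; an all-equal weight map
  scales to all zeros rather than dividing by zero.
* A grand average with no class difference reports `t = NA` ("no effect")
  instead of erroring; participants missing a class are excluded with a
  warning.
* `makeFolds()` refuses degenerate plans (a fold with an empty training
  set, e.g. one trial per class).
* CSP truncates near-null directions of the composite covariance instead
  of ridging by default; an explicit ridge is available for rank-deficient
  input.
* Weight-map averaging order is absolute value first, then mean over maps,
  models, and finally min-max scaling — signed kernels must not cancel.

## Problem sizes used by the checks

The packaged checks run on synthetic data sized for interactive use:
calibration checks at 400 trials; protocol and recovery checks at 60–100
trials per dataset with 5–10 generator seeds; the grand-average checks at
8 simulated participants of 40 trials. The acceptance script regenerates
everything it reports at run time from its `--seed`.

## Known limitations

* The generator's linear class signal compresses the achievable spread
  between classifiers (see above); it stresses the pipeline and protocol,
  not the network's representational advantage.
* EOG regression assumes linear, stationary propagation; ICA-style
  separation, notch filtering and bad-channel interpolation are out of
  scope.
* The EDF writer targets fidelity and round-tripping (16-bit, one-second
  records, a reserved-field sample-count hint); it is not a validated
  clinical EDF implementation.
* The response-bias statistic is an interpretation; participant selection
  on real datasets should confirm the intended definition.
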