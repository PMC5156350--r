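# conveegnn

Predicting whether a studied event will later be **remembered or forgotten**
from the single-trial EEG recorded around the event.

During learning, EEG differs systematically between events that will later
be remembered and those that will be forgotten — the *subsequent memory
effect* (SME): frontal sites show a more negative-going potential in the
1.5 s cue–word interval and a more positive-going one while the word is
heard. This package turns that group-level effect into a single-trial
prediction problem: given one trial's `N_ch × T` voltage matrix `I`, learn
`H : I → Z` with `Z ∈ {remembered, forgotten}`.

## The model

The core classifier, **ConvEEGNN**, is a five-layer convolutional network
built for this input:

| layer | operation | size / parameters |
|---|---|---|
| `L_in` | input `I` | `N_ch × T` (30 × 75 at 25 Hz) |
| `L_c`  | spatial convolution: kernels span all `M = N_ch` channels at one time index, stride 1 | `N_c` maps × `T`; `N_c (M+1)` params |
| `L_cs` | temporal convolution + subsampling: kernel length `K_m = T / P_m`, stride `K_m` (non-overlapping) | `P_m` outputs per map; `Σ (K_m+1)` params |
| `L_h`  | dense, logistic | `Q = 10`; `Q (Σ P_m + 1)` params |
| `L_out`| dense, logistic | `(Z0, Z1)`; `2 (Q+1)` params |

Convolutional layers use the scaled tanh `f(u) = 1.7159 tanh(2u/3)`; a trial
is predicted *forgotten* iff `Z0 > Z1`. Training is per-sample SGD on the
half squared error with one-hot targets, a stratified 70/30
train/validation split, cyclic duplication of the minority class, and early
stopping at the validation-MSE minimum.

Around the network: the six-step ERP preprocessing chain (linked-mastoid
re-reference, 0.05–15 Hz zero-phase band-pass, EOG regression, `[-0.1, 2.9)` s
epochs, baseline correction, ±50 µV artifact rejection), leave-pair-out
cross-validation with exact binomial significance against chance, six
comparison classifiers (LDA, ANN-1/ANN-2, cubic-polynomial SVM, a
CSP/SVM + LDA fusion, Morlet band power + L1 linear), channel weight-map
analysis of the learned spatial kernels, and a calibrated synthetic SME
session generator (EDF/BrainVision writers included) so the whole pipeline
runs with no external data.

## Worked example

```r
library(conveegnn)

cfg     <- simConfig(nTrials = 60, noiseSigma = 3, seed = 7)
session <- simulateSession(cfg)        # continuous 32-channel recording
epochs  <- preprocessSession(session)  # six-step chain, labeled epochs
epochs
#> EpochSet: 55 trials x 30 channels x 1500 samples at 500 Hz
#>   labels: 30 remembered / 25 forgotten; 5 rejected
#>   provenance: simulated -> rereference -> bandpass[0.05-15] ->
#>     eog-regression -> segment -> baseline -> reject[50]

crossValidate(epochs, classifierSpec("lda"), window = "entire", seed = 7)
#> CVResult [lda, entire window]: accuracy 83.64% (46/55), p = 2.168e-07 *

fit <- trainNetwork(prepareInput(epochs, "entire"),
                    cfg = networkConfig(nC = 1, p = 3, seed = 7))
#> TrainResult: stopped at epoch 201, best epoch 176 (val MSE 0.12013)

topChannels(weightMap(fit, chNames = channelNames(epochs)), 3)
#> [1] "F8"  "Fp2" "C3"
```

Five trials were rejected (the generator plants drift artifacts), the
linear baseline decodes the planted ±2 µV window effects well above chance
at this noise level, and two of the network's top-3 weight-map channels
fall in the frontal group carrying the effect.

A command-line interface wrapping these functions ships in
`inst/cli/conveeg.R` (subcommands `simulate`, `preprocess`, `train`,
`evaluate`, `analyze-channels`, `sme-report`, `run`).

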