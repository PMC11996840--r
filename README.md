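# emgmonitor

Onset/offset detection ("activity monitoring") for single-channel surface
electromyography (EMG). The package is aimed at researchers in
biomechanics, ergonomics, rehabilitation and human–machine interaction who
need the *temporal* structure of muscle activity — when a contraction
starts and when it ends — rather than gesture classification.

## What it implements

The core signal feature is the Teager–Kaiser energy operator and its
multi-resolution generalization. For a discrete signal `x_n`:

- **TKEO**: `Ψ(x_n) = x_n² − x_{n+1} x_{n−1}`, an instantaneous
  frequency-weighted energy (`≈ ω²A²` for a sinusoid of amplitude `A` and
  angular frequency `ω`);
- **k-TEO**: `Ψ_k(x_n) = x_n² − x_{n+k} x_{n−k}`, the lag-`k` version,
  more sensitive to lower frequencies as `k` grows;
- **MTEO**: `p_n = max(Ψ_1(x_n), …, Ψ_k(x_n))`, max-pooling across scales
  so that energy is captured over the whole EMG band. Full-wave rectified
  ("a"-prefixed) variants take `|Ψ_k|` before pooling.

After median conditioning of the energy series (order statistics remove
the spikes the operator produces on noise), two monitors turn energy into
alternating onset/offset change-points:

- **MEOTD** — a double-threshold detector. An amplitude threshold
  `Th1 = mean(M) + j·mean(Std)` is estimated from frame statistics of an
  activity-free baseline prefix; an onset requires `Ton` (default 100 ms)
  consecutive supra-threshold samples, an offset `Toff` (default 30 ms)
  consecutive sub-threshold samples — the minimum contraction duration and
  switching time of muscle physiology.
- **MEONND** — a fixed-weight network-style detector needing no baseline
  prior: energy "convolution" channels with frozen neuron weights
  (algebraically identical to `Ψ_k`), max pooling, median conditioning, a
  min-max sampling layer mapping energy to `[0, 1]`, a sigmoid + hard
  limiter at threshold `T` (default 0.506), and removal of activations
  shorter than 30 ms.

Detections are scored by a region-based revised confusion matrix: each
true change-point owns a valid-detection interval from 300 ms before to
200 ms after it; exactly one correctly-typed event there is a TP, none is
an FN, anything else an FP; empty baseline/activity regions count one TN
each and stray events one FP each. From the counts come Onset/Offset TPR,
a pooled F1 (0–100) and onset/offset bias (RMSD, ms), which an Analytic
Hierarchy Process (AHP) model folds into one tunable score

```
AHP = w1·OnsetTPR + w2·OffsetTPR + w3·F1 − w4·OnsetBias/1e5 − w5·OffsetBias/1e5
```

with weights derived from a 5×5 pairwise judgment matrix
(row-geometric-mean eigenvector, consistency-checked via λmax/CI/CR).
`tune_detector()` runs the exhaustive parameter search this score ranks.

A seeded synthetic generator (`simulate_emg()`) produces labelled
recordings — Gaussian baseline plus band-limited (20–450 Hz) stochastic
bursts with trapezoidal envelopes at a chosen SNR — so every stage is
testable without access to clinical data.

## Worked example

```r
library(emgmonitor)
rec <- simulate_emg(duration = 30, n_bursts = 8, seed = 42)  # 20 dB SNR
fit <- detect_activity(rec, "meonnd")
fit
#> <MEONND detection> 8 bursts in 30 s at 1024 Hz
#> parameters: k_max=15 L=15 threshold=0.506 min_on_ms=30 rectified=FALSE normalization=global
head(fit$events, 4)
#>    event    time_s index
#> 1  onset  5.026367  5148
#> 2 offset  6.875977  7042
#> 3  onset  9.882812 10121
#> 4 offset 11.769531 12053
evaluate_detection(fit, rec)
#> <emg_metrics>
#>   Onset TPR  100.00%   Offset TPR 100.00%   F1 100.00
#>   Onset bias 11.9 ms   Offset bias 10.0 ms
#>   pooled counts:  TP=16 TN=17 FP=0 FN=0
```

All 8 simulated bursts are recovered (16 change-points), every onset
within ~12 ms RMS of the labelled ramp start, with no false or missed
events. The AHP weight derivation is equally direct:

```r
ahp_weights()
#> <ahp_weights> n=5  lambda_max=5.0133  CI=0.0033  RI=1.11  CR=0.003 (consistent)
#>             onset_tpr offset_tpr     f1 onset_bias offset_bias
#> eigenvector    1.7826     1.7826 1.0000     0.5610      0.5610
#> weight         0.3134     0.3134 0.1758     0.0986      0.0986
```

A command-line front end for shell pipelines lives in
`inst/cli/emgmon.R` (subcommands `simulate`, `detect`, `evaluate`,
`tune`); see `?run_cli`.

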