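---
title: "EMG activity monitoring with multi-resolution energy operators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EMG activity monitoring with multi-resolution energy operators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgmonitor)
```

## The problem

Surface EMG localization asks *when* a muscle is active: the onset and
offset change-points that bound each voluntary contraction. Downstream
uses — prosthesis control, ergonomic load analysis, clinical gait timing —
need those instants to within tens of milliseconds, from a signal whose
active segments are stochastic, band-limited (roughly 20–450 Hz at the
usual 1 kHz-class sampling rates) and separated by a noisy baseline.

This package treats detection as energy thresholding after a nonlinear
conditioning step, plus a scoring and tuning framework around it.

## Energy operators

The Teager–Kaiser operator estimates instantaneous frequency-weighted
energy from three samples: `Ψ(x_n) = x_n² − x_{n+1}x_{n−1}`. On a pure
sinusoid `A·cos(ωn)` the interior output is exactly `A²sin²(ω) ≈ ω²A²`,
which is what makes it attractive for EMG: bursts carry both more
amplitude and more high-frequency content than baseline, and both are
amplified quadratically. The lag-`k` generalization
`Ψ_k(x_n) = x_n² − x_{n+k}x_{n−k}` (interior output `A²sin²(kω)`) shifts
the sensitivity toward lower frequencies; the multi-resolution operator
(MTEO) pools them, `p_n = max_k Ψ_k(x_n)`, so that no part of the EMG
band is missed. These identities are not just motivation — the test suite
uses them as closed-form oracles (`A²sin²(kω)` to 1e-9 relative, against
a brute-force loop implementation exactly).

Two conventions are deliberate:

* **Boundaries.** Where `x_{n±k}` would leave the recording the operator
  output is 0, and the pooled maximum at a near-boundary sample ranges
  only over the scales defined there. No samples are fabricated, and
  boundary zeros never enter the maximum (which matters when unrectified
  energies are negative).
* **Scale set.** Pooling uses every integer scale `1..k_max`. Tuning
  grids traverse odd `k` only (a sampling of the same axis), but the
  pooled set itself is complete; an explicit `scales =` argument exposes
  the odd-only alternative for comparison.

Energy operators spike on noise (the classical amplitude/frequency
demodulation interpretation degenerates when the denominator energy
approaches zero), so the series is conditioned with a *median*, not a
mean: an isolated spike moves a mean by its full weight but leaves a
median untouched. The median runs as a hop-1 centered window of length
`L` so the output stays sample-aligned with the signal; a non-overlapping
frame variant (`variant = "frame"`, which the sliding filter matches at
frame centers) is kept for frame-based pipelines. At the edges the window
shrinks symmetrically rather than padding.

## MEOTD: baseline double-threshold detection

The classical monitor assumes the recording opens with noise only. The
first `baseline_ms` (default 1000 ms) of conditioned energy are framed
(window 128, hop 64 samples — about 8 frames at 1024 Hz; the frame
statistics are means and *population* standard deviations), and

```
Th1 = mean(frame means) + j * mean(frame sds)
```

with `j` the threshold scaling factor (default 5, grid 1–10). Onset
requires `Ton` consecutive samples strictly above `Th1`; offset `Toff`
consecutive samples strictly below. `Ton = 100 ms` and `Toff = 30 ms`
encode the minimum voluntary-contraction duration (≥ 100 ms) and the
minimum switching time (25–30 ms); they are stored in milliseconds and
converted with `round(ms·fs/1000)` in one utility so the detector is
sampling-rate independent. Ties at exactly `Th1` satisfy neither strict
inequality. A trailing activity that never closes is terminated at the
final sample so the output always alternates onset/offset.

## MEONND: the fixed-weight network-style detector

The second monitor rebuilds the same computation as a frozen
feed-forward network, removing the baseline prior entirely:

1. **Convolution channels** — one neuron per scale with squared
   activation, `C_k(n) = W1(w11 x_{n+k})² + W2(w22 x_n)² +
   W3(w33 x_{n−k})² + W4(w14 x_{n+k} + w34 x_{n−k})²` and frozen weights
   `W1=W2=W3=1, W4=−1, w11=w14=2, w22=1, w33=w34=1/4`. Expanding the
   squares, the `x²_{n±k}` terms cancel (`4−4`, `1/16−1/16`) and the
   cross term is `−1`, so `C_k ≡ Ψ_k` identically; the suite verifies
   this to 1e-12 relative. The layer rejects any other weights — it is a
   computation, not a trainable model.
2. **Max pooling** across channels, then **median conditioning** of the
   pooled series (same placement as in MEOTD — once, after pooling; a
   per-channel pre-pooling variant was considered and rejected as it
   changes nothing for monotone medians while costing `k_max` filter
   passes).
3. **Sampling layer** — min-max normalization to `[0, 1]`.
4. **Classifier** — logistic sigmoid then a hard limiter: active iff
   `sigmoid(y) ≥ T`. Since `y ∈ [0,1]`, the sigmoid output spans
   `[0.5, 0.7311]`, so useful `T` sit just above 0.5 (default 0.506; the
   tuning grid runs 0.406–0.506 in 0.02 steps — the nominal upper bound
   0.514 is unreachable from 0.406 with that step and is excluded; any
   `T ≤ 0.5` activates every sample). Ties activate, which keeps `T=0.5`
   on a zero input deterministic.
5. **Post-processing** — activations shorter than 30 ms (the minimum
   physiological activation) are discarded. Gaps are never merged: only
   removal is physiologically justified, and merging would couple
   adjacent bursts.

### The normalization reference — a deliberate design choice

The sampling layer's reference extremes are taken over the *whole
series* by default. A causal variant normalizing over a trailing
`2·k_max`-sample window is provided (`normalization = "causal"`) for
streaming experiments, but it cannot serve as the default: inside a
window that contains only baseline, the normalized value of stationary
noise is close to uniform on `[0, 1]`, so with any threshold in the
meaningful range (`T > 0.5` cuts at `y ≈ 0.02–0.06`) nearly every
baseline sample classifies as active, for every window length we tested
(30–4096 samples). Series-wide normalization is what makes `T ≈ 0.5` a
discriminator: at 20 dB SNR the conditioned baseline energy is about 1%
of the burst maximum, safely below the `y ≈ 0.024` cut of `T = 0.506`,
while burst energy sits well above it. The cost is that the detector, as
configured by default, is an offline (whole-recording) method; the
degree-2 homogeneity of the energy layers plus the normalization still
make it exactly invariant to global amplitude scaling, which the suite
tests as `detect(c·x) = detect(x)`.

## Scoring detections

Each true change-point owns a valid-detection interval from 300 ms
before to 200 ms after it (electromechanical delay means genuine EMG
activity precedes measured motion by up to ~260 ms; 200 ms is the limit
of imperceptible control latency). The intervals partition the recording
into baseline, onset segment, activity and offset segment, and events
are scored per region: a segment with exactly one correctly-typed event
is a TP (the pair feeds the bias estimate), an empty segment an FN,
anything else one FP; empty baseline/activity regions one TN each, and
every stray event there one FP. Counting TNs per *region* rather than
per sample keeps the four counts on comparable scales. Onsets and
offsets go through identical machinery.

From the counts: `TPR = TP/N_true` per type, pooled
`F1 = 2TP/(2TP+FN+FP)·100`, and bias as the RMSD (ms) over matched
pairs; a type with no true events or no TPs reports `NA` rather than a
fabricated zero. Two degenerate-input rules are explicit: bursts shorter
than 500 ms make their two segments abut (the boundary is their
midpoint; the activity region is empty), and truth sets whose intervals
overlap *across* bursts are refused outright because the scoring rules
are undefined there.

## AHP tuning

Five metrics cannot be maximized simultaneously, and they are not
equally important: for monitoring, a slightly biased but reliable
detector beats a sharp but erratic one. The judgment matrix encodes
exactly that ordering (TPRs ≻ F1 ≻ biases; 1–5 scale). Weights are the
normalized row geometric means — chosen over the principal eigenvector
deliberately, because for this near-consistent matrix the two agree to
four decimals on the weights while the geometric-mean eigenvector is the
one whose components are round surds (`18^{1/5} = 1.7826`), and the
method is exactly reproducible without iteration. `λmax` is the mean of
`(Aw)_i/w_i`; `CI = (λmax−n)/(n−1)`; `CR = CI/RI` with `RI(5) = 1.11`
(the convention matching the published consistency figures; some tables
use 1.12). The matrix is stored with exact reciprocals (1/3, not its
4-decimal rounding), though the validator accepts entries reciprocal to
1e-3.

The composite score consumes TPRs and F1 as fractions and biases in ms
divided by `1e5`, so a 100 ms bias costs about as much as 0.01% of TPR —
biases perturb the ranking rather than dominate it — and is monotone
increasing in every rate and decreasing in every bias (tested). Grid
search micro-averages confusion counts over all recordings per cell,
pools bias pairs, scores, and breaks ties toward smaller parameters in
column order; a failing cell scores `NA` and the search continues.

## The synthetic generator

No public labelled corpus accompanies the method, so validation runs on
a surrogate that emulates the acquisition conditions: 1024 Hz sampling,
120 s recordings with 30 voluntary contractions of 0.5–2 s. Bursts are
zero-phase band-pass-filtered Gaussian noise (4th-order Butterworth,
20–450 Hz, filtered with generous padding so edge transients never enter
the recording) scaled to `sd = baseline_sigma·10^{snr/20}` and shaped by
a trapezoidal envelope with 50 ms linear ramps; the baseline is white
Gaussian noise. The ramp start/end are the labels, giving an unambiguous
ground truth for bias. Burst separation is at least 600 ms so adjacent
valid intervals (500 ms wide) cannot collide, and a 2 s activity-free
lead-in honours the double-threshold baseline assumption. The default
SNR is 20 dB — the boundary of the "clean recording" regime the recovery
tests target.

What the surrogate does *not* model: motor-unit action-potential trains
(real EMG is an impulse process, not Gaussian), amplitude
non-stationarity within a contraction, electrode artifacts, power-line
interference, or baseline drift. Passing recovery tests therefore
demonstrate correctness of the pipeline under its stated assumptions,
not clinical-grade performance; the published real-data figures (95–97%
onset TPR, ~100–130 ms onset bias on 20 subjects) are not reproducible
without that private dataset, and the synthetic figures here (TPR 1.0,
bias ~5–15 ms at 20 dB) are *easier* than real data precisely because
the surrogate's onsets are sharp.

## Numerical choices and problem sizes

* `round(ms·fs/1000)` in one place for every ms→sample conversion.
* Median edge rule: shrinking symmetric windows; implemented on top of
  `stats::runmed` with explicit edge recomputation (the built-in end
  rules differ from this convention).
* Energy boundary samples are zero and never pollute pooling.
* Event times serialize at 6 decimals with 1-based sample indices
  alongside; indices are exact, times are display precision.
* Recovery tests use 20 seeded recordings of 120 s × 30 bursts per
  detector; oracle-equivalence tests use 200 random instances of length
  ≤ 200. Both complete in well under a minute on one core.

## Known limitations

Single-channel only; no adaptive re-estimation of the MEOTD baseline
during long recordings; MEONND's default normalization requires the full
recording (see above); the AHP judgment matrix is fixed expert input,
not elicited from data; and tuning pools all recordings
(micro-averaging) rather than averaging per-subject scores.
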