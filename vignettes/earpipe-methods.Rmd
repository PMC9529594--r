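---
title: "Methods: ear-electrode signal analysis for bruxism detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ear-electrode signal analysis for bruxism detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earpipe)
```

## The problem

Electrode arrays worn around the ear (cEEGrid-style flex-prints driven by
consumer biosignal amplifiers such as the OpenBCI Cyton + Daisy) record a
mixture of neural activity, facial-muscle EMG, power-line interference and
slow drift at a modest sampling rate (250 Hz, 16 channels). Jaw clenching —
the motor pattern of awake bruxism — produces large, bilateral EMG
signatures at the ear, which makes an inconspicuous wearable detector
plausible. The analytic difficulty is threefold: line noise is
non-stationary (it jumps when the wearer touches mains-powered equipment),
clench events are rare relative to everything else a face does, and a
detector must generalize across recording days.

`earpipe` implements the full chain: adaptive reference-channel line-noise
removal, epoch-level event labeling, a seven-feature per-channel time-domain
description, and imbalance-aware cross-session classification — together
with a synthetic-session generator so every stage is testable without
hardware or downloads.

## The synthetic-session generator

The generator emulates a posed facial-activity protocol: 28 activity
classes, exactly two of which (`clench_short`, `clench_long`) are bruxism,
posed in seeded random order over three sessions with a rest gap between
trials. Signal content per channel is the sum of

* **EEG background** — white noise spectrally shaped to power ∝ 1/f (floored
  at 1 Hz), 5 µV RMS, plus a 10 Hz alpha sinusoid (2 µV);
* **EMG bursts** — one band-limited (20–100 Hz) unit-RMS noise source per
  trial, gated by 50 ms raised-cosine ramps and projected onto the montage
  by an activity-specific spatial gain row (a Gaussian bump over channels;
  jaw clenches project bilaterally at 25 µV peak versus 8 µV for other
  activities, reflecting the large masseter/temporalis EMG seen at the ear);
* **line interference** — a 50 Hz sinusoid whose amplitude is 1 µV at
  baseline plus 10 µV during scheduled bursts (5 s every 30 s by default),
  coherent across channels and multiplied by 20 on an optional "open"
  (taped-off) electrode that records no physiology;
* **baseline wander** — common-mode noise shaped to below 0.5 Hz, 3 µV RMS.

Unstated protocol timings were fixed once: 2 s per activity (4 s for the
long clench) and 2 s rest. With 29 trials per activity a session spans
3306 s — matching the reported order of ~3,300 one-second epochs per
session — and bruxism occupies ~5 % of samples, the same minority-class
regime as the real study (which reports 8 %). Whether the two clench
classes differ in intensity as well as duration is not documented; they are
modeled with equal gain and different duration.

What the generator does **not** model: volume-conducted dipole physics,
electrode impedance drift, accelerometer/movement artifacts, ERP or sleep
signatures, or cross-talk between concurrent activities. Passing tests
therefore demonstrate that the *pipeline machinery* is correct and that the
method recovers events whose statistical structure matches its assumptions —
not that the trained model transfers to real recordings.

## Line-noise removal: notch vs NLMS

The normalized least-mean-squares canceller predicts the contaminated
channel from a reference (the open electrode) through an adaptive FIR of
`round(0.25 s × fs)` taps, with update
`w ← w + µ e(n) r(n) / (‖r(n)‖² + ε)`, zero-initialized weights, ε = 1e-8,
and pass-through of the first `n_taps` samples where the regressor is
undefined. A rolling mode resets the weights every 2 s so slow trends are
not learned.

A point that matters for interpretation: with a (quasi-)sinusoidal
reference, an LMS-family canceller is equivalent to an adaptive notch whose
bandwidth grows with the learning rate, and its steady-state misadjustment
adds broadband noise of order µ/(2−µ) times the unpredictable signal power.
At µ = 1 — a common choice for fast tracking — the equivalent notch spans
tens of hertz and out-of-band power rises ~3 dB, i.e. fast adaptation
*re-creates* the spectral band hole that the adaptive approach is meant to
avoid. `nlms_clean()` keeps µ = 1 as its default (fast tracking of bursty
interference, the conventional setting for this hardware), while
`compare_line_noise_removal()` — whose purpose is the spectrum-preserving
contrast against a 251-tap FIR notch — runs at µ = 0.1, where measured
behavior is ≥ 20 dB attenuation of the 50 Hz bin, < 0.5 dB change in the
5–40 Hz band, and mean PSD in 45–55 Hz several times the notch filter's
49–51 Hz residual. Both filters are scored after a 1 s settling period.

Preprocessing filters are an order-4 Butterworth band-pass (5–62 Hz) and a
second-order IIR notch (quality factor 30) — the text behind them specifies
only "IIR", so conventional minimal designs were chosen — applied
forward–backward. Zero-phase application avoids latency shifts of event
energy relative to the 1 s epoch grid; it is also why a criterion on filter
attenuation is evaluated in steady state rather than at epoch edges. Welch
PSDs use 1 s Hann-tapered segments with 0.5 s overlap, per-segment mean
removal and mean-power normalization.

## Epoching and labeling

Samples inside `[onset + 0.35 s, offset + 0.35 s)` of a clench annotation
are positive; the 350 ms shift compensates the wearer's reaction time to the
cue, and is applied to both onset and offset (the source text does not say
which; both-shifted is the symmetric reading and is configurable).
Interval-to-sample conversion is half-open with `ceil(t × fs)` start
indices — one fixed, testable convention. Epochs tile the session in
non-overlapping 1 s windows anchored at sample 0 (mimicking an online
detector; no alignment to trial onsets), the trailing partial window is
dropped, and an epoch is positive iff **at least** 50 % of its samples are
positive — the boundary is inclusive, so 125 of 250 samples label the epoch
positive and 124 do not.

Per-epoch preprocessing (mean-centering, band-pass, notch, in that order)
follows the online-detector framing at the cost of filter edge effects on
250-sample segments; zero-phase application mitigates this, and a
session-scope alternative (`preprocess = "session"`) filters each whole
channel once before epoching.

## Features

Seven time-domain features per channel and epoch, computed after
mean-centering, in fixed column order `activity, complexity, mobility,
abs_max, abs_sum, higuchi_fd, petrosian_fd` (16 channels × 7 = 112 columns):

* **Hjorth activity** = population variance (n-denominator, fixed for
  oracle equivalence); **mobility** = `sqrt(var(Δx)/var(x))`;
  **complexity** = mobility(Δx)/mobility(x). A flat epoch returns (0,0,0).
* **Absolute amplitude maximum / sum** — `max|x|` and `Σ|x|`; the sum is not
  length-normalized (epochs have constant length, so this is a mean up to
  scale).
* **Higuchi fractal dimension** — slope of ln L(k) on ln(1/k) over
  k = 1..10; k_max = 10 is the common default for ~250-sample windows
  (unstated in the source). Constant input is defined as 1.
* **Petrosian fractal dimension** —
  `log10(n) / (log10(n) + log10(n/(n + 0.4 N_δ)))` with `N_δ` the sign
  changes of the first difference; exact zeros in the difference are
  ignored (changes counted between nearest nonzero neighbors), removing the
  measure-zero ambiguity, so monotone and flat signals give exactly 1.

Mobility, complexity and both fractal dimensions are scale-invariant;
activity scales quadratically and the amplitude features linearly; all
features are shift-invariant through the mean-centering — these invariances
are enforced by property tests against straight-loop re-implementations.

## Classifier and evaluation

Two sessions train, the third is held out — a cross-session split, which is
the harder and more honest test for a wearable. On the pooled training
epochs:

1. **Stratified 5-fold CV** selects `n_estimators` from {50, 100, 200} by
   mean F1. Folds preserve the class ratio to within one epoch.
2. **SMOTE** balances classes (synthetic minority rows drawn uniformly on
   segments to one of k = 5 nearest minority neighbors, Euclidean metric),
   fitted *inside* each CV training fold and once on the full training set
   for the final model — pre-split oversampling would leak validation
   information.
3. **z-standardization** uses training-set means/SDs only; constant columns
   map to 0 with a warning.
4. The classifier is adaptive boosting (discrete SAMME stage weights,
   `α = log((1−err)/err)`) over depth-1 `rpart` trees; prediction is the
   sign of the weighted vote (fixed 0.5 threshold, no tuning). No AdaBoost
   implementation ships with the available stack, so the boosting loop is
   implemented here over `rpart` weak learners and checked on separable and
   label-permuted fixtures.

Reports carry TP/FP/FN/TN, precision, recall, F1 and Matthews correlation
coefficient, with every 0/0 defined as 0. MCC is the headline number:
it uses all four confusion cells and is stable under the ~5–12 % positive
prevalence this problem has.

## Problem sizes used by tests and the acceptance script

The generator's scientific conditions (durations, gains, noise amplitudes,
28 activities, 3 sessions) are identical everywhere; only the number of
trials per activity is scaled to keep runtimes proportionate: 29 (full
protocol, ~3306 epochs/session) for the arithmetic checks, 5 trials
(~570 epochs/session) for the cross-session classification run with CV, 3
for the permutation-null recovery test, and 2 (~228 epochs/session, 5 seeds
× 3 EMG gain scales 0.1/0.3/1.0) for the SNR-monotonicity check. At the
default gains the synthetic problem is nearly separable (F1 ≈ 1 on the
held-out session); the gain sweep spans failure (F1 ≈ 0.2) to saturation,
which is the regime the monotonicity property probes. Real-data performance
(the multi-session study reports F1 0.73 on a held-out day) sits between
these extremes and cannot be reproduced from synthetic data; the published
recordings can be run through the same entry points (`cmd_run`) unchanged.

## Numerical and degenerate-input conventions

* Intervals are half-open `[start, end)`; start index `ceil(start × fs)`
  (0-based), with a 1e-9 guard against floating-point edge jitter.
* NLMS: first `n_taps` samples pass through; reference ≡ 0 returns the
  primary unchanged; µ outside (0, 2] is rejected.
* Welch: signal shorter than one window is an error; zero signal gives an
  identically zero PSD.
* Boosting stops early at zero weighted error or when no stump beats
  chance; a single-class training set is an error, as is SMOTE on one
  class. SMOTE reduces k (with a message) when the minority class has ≤ k
  members.
* All randomness flows through explicit integer seeds (`withr::with_seed`),
  so identical configs + seeds give byte-identical studies, folds, SMOTE
  draws and reports.

## Known limitations

* The synthetic EMG spatial model is a smooth gain bump, far simpler than
  real volume conduction; classifier scores on synthetic data overstate
  real-world performance.
* Per-epoch filtering of 250-sample windows limits achievable notch depth
  (~16 dB at 50 Hz measured on epochs vs > 27 dB on whole sessions).
* The NLMS misadjustment/bandwidth tradeoff means no single learning rate
  both tracks second-scale interference bursts and preserves the spectrum
  within 1 dB; the two entry points default to different regimes and state
  so.
* Only binary (bruxism vs rest-of-world) labels are produced; the
  multi-class structure of the protocol is retained solely as epoch
  metadata.
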