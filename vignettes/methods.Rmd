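---
title: "Wavelet sub-band entropy features for PD/HC EEG classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet sub-band entropy features for PD/HC EEG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegdwt)
```

This vignette explains the model behind `eegdwt`, the parameters that matter,
what the synthetic cohort generator does and does not emulate, and the design
choices made where reasonable implementations could differ.

## The pipeline

Resting-state EEG from PD patients differs from healthy controls in the power
distribution and complexity of its rhythms, both in the classic low bands and
— less intuitively — in high-frequency activity. The pipeline turns a
multichannel recording into per-segment feature vectors:

1. **Band-pass** 0.5–32 Hz, fifth-order Butterworth, zero phase. Most of the
   discriminative power of PD/HC EEG lives below 32 Hz, and the high-pass edge
   removes drift.
2. **Segmentation** into non-overlapping `T`-second windows (10 s for
   minutes-long recordings, 2 s when recordings are only a minute, to keep
   enough vectors). Trailing partial windows are dropped.
3. **DWT decomposition/reconstruction.** Each channel segment is decomposed
   4 levels deep with db4. Rather than computing features from the coefficient
   vectors (whose lengths shrink dyadically, losing time resolution at low
   frequencies), the signal is *reconstructed from each coefficient set
   separately*, yielding five full-length band-limited signals per channel —
   cA4 plus cD4…cD1, covering (0, fs/32), (fs/32, fs/16), … (fs/4, fs/2).
4. **One complexity measure** is evaluated on each of the five sub-band
   signals and on the raw segment: 6 features per channel, channel-major
   order, 6·ch per vector (192 for 32 channels).
5. **Classification** with fixed, deliberately simple settings (below), and
   evaluation by repeated stratified 10-fold CV (intra-subject) and LOSO CV
   (inter-subject).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `low_hz`, `high_hz` | 0.5, 32 Hz | band-pass edges; `high_hz` must stay below fs/2 |
| `order` | 5 | Butterworth order; zero-phase application squares the magnitude response |
| `T` | 2 or 10 s | window length; T·fs must be integral |
| `mother`, `level` | db4, 4 | wavelet and depth; level is held at 4 regardless of fs, so band edges scale with fs |
| `alpha` | 0.2 | threshold-entropy cutoff, on the same scale as the (µV) signal; must be < 1 |
| `p` | 1.1 | norm-entropy exponent, ≥ 1 |
| `pound` | 3 | sure-entropy threshold, > 2 |
| `t_min`, `t_max` | 0, 255 | intensity-transform range (8-bit image convention) |
| `knn_k` | 3 | KNN neighbours, euclidean distance |
| `svm_C` | 0.2 | least-squares SVM regularisation; quadratic kernel by default |
| `rf_n_learners` | 30 | bagged trees |
| `k`, `repeats` | 10, 10 | CV folds and rounds |

## Interpretation of the entropy formulas

The measure definitions are written over values $x_i$ with an index bound
$k$. Two readings exist: $x_i$ as the raw samples ($k = N$), or $x_i$ as the
relative frequencies of the $k$ *unique* values. On continuous-valued
reconstructed signals every sample is unique, which makes the
frequency reading degenerate (all $p_i = 1/N$, so ThEn/NoEn/SuEn/LogEn/ShEn
would collapse to constants depending only on $N$). The package therefore
defaults to the **sample** reading for those five measures — which is also
how the classic MATLAB wavelet-entropy utilities behave — and to the
**unique-frequency** reading for TShEn, whose quantized 0–255 output makes
unique-value frequencies well defined and matches the $1/k$ normalisation in
its definition. Both modes are implemented and switchable
(`measure_spec(value_mode=)`); this is the largest ambiguity in the method
and the single choice most likely to change absolute feature values.

Related conventions, applied exactly as printed unless noted:

* Shannon entropy is used **without** a leading minus (the as-printed form);
  `negate_shannon = TRUE` restores the conventional sign.
* Natural logarithms everywhere; $\log 0$ and $0 \log 0$ terms contribute 0.
* ThEn counts strictly $|x_i| > \alpha$; SuEn counts $|x_i| \le t$.
* The intensity transform is applied to the sub-band signal's raw amplitudes.
  On µV-scale EEG most samples fall outside $[0, 1]$ and clip to 0 or 255;
  that heavy clipping is part of the method (the transform was designed on
  this scale), and an optional min–max pre-normalisation is deliberately NOT
  applied by default. Quantisation rounds half-up, emulating 8-bit image
  intensities.
* Accuracy and the other ratios are reported in percent. A ratio with a zero
  denominator is reported as `NA`, never silently as 0.

## Numerical choices

**Zero-phase filtering as a biquad cascade.** The single transfer-function
form of an order-5 band-pass with a 0.5 Hz lower edge is numerically
*unstable* at EEG sampling rates: under double-precision coefficient
rounding one pole lands just outside the unit circle. The filter is therefore
designed from the analog Butterworth prototype (exact pole formulas, band
transform, bilinear transform) and factored into second-order sections, then
applied forward–backward with odd-reflection padding and steady-state initial
conditions. Linearity holds to ~1e-13 and the DC response is exactly zero.
One caveat inherent to zero-phase filtering with a very low high-pass edge:
edge discontinuities excite the slow 0.5 Hz poles, whose ringing decays over
seconds. Magnitude-response assertions (and steady-state windows for
time-domain checks) are the appropriate oracles for stop-band behaviour, not
whole-window RMS on short signals.

**DWT boundary handling.** Symmetric (half-point) extension, the common
default of the MATLAB `wavedec` tool chain; coefficient lengths follow
$\lfloor (n + F - 1)/2 \rfloor$ with the 8-tap db4 filter. Reconstruction is
exact to < 1e-8 on lengths 256–8192, and the five reconstructions sum to the
original signal by linearity of the inverse transform (verified property,
not an assumption). Energy across the five signals is conserved to within 1%
(orthogonality up to boundary effects). The tree is a plain DWT — only
approximations split — although the reconstructed signals are referred to as
"WP signals" following common usage in this literature.

**Least-squares SVM.** "Least squares" SVM with a quadratic kernel and
C = 0.2 is solved directly as the LS-SVM linear system
$[[0, \mathbf{1}^\top],[\mathbf{1}, K + I/C]]\,[b;\alpha] = [0;y]$ with
$K = (x^\top y/d + 1)^2$ (dimension-scaled for conditioning). Features are
standardised with training-fold statistics for all classifiers (KNN distances
and kernel scales are meaningless across raw feature magnitudes spanning
orders of magnitude); the standardisation is computed inside each fold, so no
information leaks from test to train.

**Cross-validation.** Folds are stratified (class proportions preserved) and
reshuffled each repeat from a seeded RNG; identical seeds give identical
folds, scores, and reports. The reported ± is the standard deviation over all
k·repeats fold scores. LOSO holds out all segments of one subject per fold;
with one subject per class LOSO is undefined (each training split would be
single-class), so at least two subjects per class are required. Inside
forward addition, every channel subset is evaluated with the *same* seeded
folds so that subset comparisons are not confounded by fold noise; a single
10-fold round is used there for tractability (configurable).

**Forward addition.** Pure greedy forward selection over per-channel feature
blocks; ties break toward the lower channel index; the per-size best accuracy
is *not* forced monotone (adding channels can hurt). For n channels the trace
costs exactly n(n+1)/2 evaluations.

**KNN ROC scores.** The continuous score for ROC/AUC is the fraction of the
k = 3 neighbours voting for the PD class (the natural posterior estimate for
a voting classifier); AUC is the Mann–Whitney statistic with rank-averaged
ties.

## The synthetic cohort generator

Each channel is $1/f$ background noise (spectrally shaped, exponent 1 by
default) plus four band-limited noise components (delta 0.5–4, theta 4–8,
alpha 8–13, beta 13–30 Hz; order-4 Butterworth-filtered white noise, so the
entropy measures see stochastic rhythms rather than deterministic tones).
Class effects are power multipliers on the band components of the informative
channels; each subject additionally draws a lognormal per-band gain
(mean 1, log-sd 0.15) that is constant across that subject's recording,
giving the stable subject signature that makes LOSO evaluation meaningful.
Defaults: 8 channels, 256 Hz, rhythm-dominated mix (background sd 1 µV,
component sd 3 µV at unit gain), so a band-power gain maps nearly linearly
onto the measured band-power ratio.

Three canonical benchmarks fix the study conditions: **easy** (2 × 10
subjects, 60 s, 3× alpha + 2× beta gain on all channels), **medium** (same,
gain on channels 2/5/7 of 8 only), and **null** (no class difference). The
null fixture uses 2 × 20 subjects × 30 s and sets the subject-level gain
variability to zero: with subject signatures present, segment-level k-fold
classification exceeds chance on label-free data simply by recognising which
subject a held-out segment came from — the intra-subject leakage that is the
standard argument for LOSO evaluation — which would defeat the fixture's
purpose as a permutation null. (Measured: 52–62% "null" accuracy with
subject gains on, 48–50% with the exchangeable construction.)

What the generator does **not** emulate: real electrode topography and
inter-channel correlation, artifacts (blinks, EMG, line noise),
non-stationarity within a recording, and the actual spectral signature of PD.
Passing the synthetic benchmarks therefore demonstrates that the pipeline
recovers planted sub-band power structure, stays at chance when none exists,
and attributes signal to the correct channels — not that any particular
clinical accuracy would be attained on real recordings, which in published
practice also depends on dataset-specific preprocessing the package assumes
has already been done upstream (artifact removal, re-referencing).

## Problem sizes used in the checks

The test suite and the acceptance script run the full pipeline on the
benchmarks above (600 segments, 8 channels, 48 features), exercise the
structural laws at full width (32 channels, 54 subjects, 528 forward-addition
evaluations — with a cheap deterministic evaluator where only the count and
trace structure are at stake), verify the eight measures against naive
formula evaluation on 1000 random vectors in both value modes, and check
wavelet reconstruction on signals of 256–8192 samples. These sizes were
chosen to exercise every code path at realistic width while keeping a full
run in minutes on one core.

## Known limitations

* EDF reading covers the standard 16-bit EDF layout (the common case for
  public EEG datasets); EDF+ annotations and discontinuous records are not
  parsed.
* The band-pass keeps 0.5–32 Hz, yet levels cD1–cD3 of a 512 Hz recording
  nominally cover 32–256 Hz. After filtering, those sub-band signals contain
  mostly transition-band residue; the pipeline reproduces this structure as
  specified and leaves its interpretation to the analyst.
* LDA and LR are run at library defaults; with hundreds of collinear features
  LR in particular can separate perfectly and its warnings are suppressed by
  design. These two are included for comparison, as the weaker baselines they
  are in this feature space.
* The LS-SVM solve is O(n³) in the number of training rows; fine at the
  hundreds-of-segments scale this pipeline targets.
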