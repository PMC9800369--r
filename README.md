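# eegdwt

Wavelet sub-band entropy features and machine-learning classification for
resting-state EEG, aimed at discriminating Parkinson's disease (PD) from
healthy controls (HC).

## What it does

Clinical interest in EEG-based PD detection comes from EEG being cheap,
portable, and fast relative to imaging. A well-studied recipe is: band-pass
the multichannel recording, cut it into fixed windows, decompose each window
into frequency sub-bands, summarise each sub-band with a complexity measure,
and feed the resulting feature vectors to standard classifiers. `eegdwt`
implements that whole pipeline:

1. **Preprocessing** — 0.5–32 Hz fifth-order Butterworth band-pass (zero
   phase, applied as a biquad cascade), non-overlapping segmentation into
   `T`-second windows.
2. **Wavelet sub-band decomposition** — a 4-level db4 DWT per channel,
   followed by *per-coefficient reconstruction*: each coefficient set (cA4,
   cD4, cD3, cD2, cD1) is inverse-transformed with the others zeroed, giving
   five full-length band-limited signals per channel (0–16, 16–32, 32–64,
   64–128, 128–256 Hz at fs = 512).
3. **Feature extraction** — one measure per sub-band signal plus the raw
   segment (6 features per channel). Eight measures are provided:

   | measure | definition (natural log; 0-terms contribute 0) |
   |---|---|
   | Eng   | Σ &#124;xᵢ&#124;² |
   | LBP   | log(N⁻¹ Σ &#124;xᵢ&#124;²) |
   | ThEn  | #{i : &#124;xᵢ&#124; > α}, α = 0.2 |
   | NoEn  | Σ &#124;xᵢ&#124;ᵖ, p = 1.1 |
   | SuEn  | k − #{i : &#124;xᵢ&#124; ≤ t} + Σ min(xᵢ², t²), t = 3 |
   | LogEn | Σ log xᵢ² |
   | ShEn  | Σ xᵢ² log xᵢ² |
   | TShEn | intensity-transform to [0, 255], then k⁻¹ Σ pᵢ² log pᵢ² over the k unique values' frequencies pᵢ |

   TShEn first maps each sample through an image-style intensity transform
   (x > 1 ↦ 255, x < 0 ↦ 0, else 255·x, rounded), which bounds the signal
   and collapses it onto at most 256 unique values so that a histogram-based
   normalized Shannon entropy is well defined.
4. **Classification and evaluation** — KNN (k = 3, euclidean), least-squares
   SVM (quadratic or linear kernel, C = 0.2), random forest (30 bagged
   trees), LDA, and logistic regression; accuracy / sensitivity / specificity
   / precision / F-score (in percent), ROC and AUC; repeated stratified
   10-fold CV and leave-one-subject-out (LOSO) CV.
5. **Channel selection** — greedy forward addition over the 6-feature channel
   blocks: n(n+1)/2 classifier evaluations for n channels (528 for 32).
6. **Synthetic cohorts** — a seeded generator of two-class multichannel EEG
   (1/f background plus band-limited delta/theta/alpha/beta components with
   class- and subject-level power gains) so the full pipeline is testable
   without any clinical recordings. Real data can be read from EDF files or
   delimited matrices with a JSON metadata sidecar.

## Worked example

```r
library(eegdwt)

spec <- synthetic_spec(n_subjects_per_class = 4, ch = 4, duration_s = 30,
                       seed = 42)
cohort <- generate_cohort(spec)
cohort[[1]]
#> <eeg_recording> HC_s01 [HC] 4 ch x 7680 samples @ 256 Hz (30.0 s), eyes unknown

segments <- bind_segment_sets(lapply(cohort, function(r)
  segment_recording(bandpass_filter(r, filter_spec()), T = 2)))
fm <- build_feature_matrix(segments, measure_spec("LogEn"), wavelet_spec())
dim(fm)   # 120 segments x (24 features + label + subject)

report <- kfold_cv(fm, classifier_spec("KNN"), k = 10, repeats = 10, seed = 42)
report
#> <eval_report> KNN, kfold_repeated, 100 folds, seed 42
#>   accuracy      98.42 +/- 3.49
#>   sensitivity   96.83 +/- 6.99
#>   specificity  100.00 +/- 0.00
#>   precision    100.00 +/- 0.00
#>   f_score       98.25 +/- 3.89
#>   auc           99.45
```

The default synthetic PD class carries a 3× alpha and 2× beta band-power
gain, so the log-energy features of the cA4/cD4 sub-bands separate the
classes almost perfectly: mean 10-fold accuracy 98.4% over 100 folds, with
sensitivity the PD detection rate and specificity the HC rate. Forward
addition then ranks channels:

```r
trace <- forward_addition(fm, classifier_spec("KNN"), seed = 42)
trace
#> <selection_trace> KNN, 10 evaluations
#>   m= 1 acc  93.33%  + ch2
#>   m= 2 acc  97.50%  + ch3
#>   m= 3 acc  98.33%  + ch1
#>   m= 4 acc  98.33%  + ch4
```

`max_acc[m]` is the best CV accuracy using m channels; with every channel
informative here, two channels already reach 97.5%.

A command-line wrapper covering the same stages is installed at
`inst/cli/eegdwt` (subcommands `simulate | extract | evaluate |
select-channels`, YAML configuration).

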