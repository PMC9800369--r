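# Seeded synthetic EEG cohort generator: two-class multichannel recordings
# with controllable sub-band power differences and subject-level variability,
# standing in for real PD / HC datasets in tests.
#
# Each channel is 1/f^exponent background noise plus one band-limited noise
# component per classic EEG rhythm (delta 0.5-4, theta 4-8, alpha 8-13,
# beta 13-30 Hz). Band components are filtered white noise, not sinusoids, so
# entropy measures see realistic complexity. Class effects are power
# multipliers on the band components of the informative channels; each subject
# additionally draws a lognormal per-band gain (mean 1), giving the stable
# subject signature that makes LOSO evaluation meaningful.

.synth_bands <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
                     beta = c(13, 30))

#' Synthetic cohort settings
#'
#' @param n_subjects_per_class Subjects per class (classes are balanced).
#' @param ch Number of channels.
#' @param fs Sampling rate in Hz (default 256).
#' @param duration_s Recording length per subject in seconds.
#' @param class_band_gains Named list, one numeric vector of relative power
#'   multipliers per class over the bands delta/theta/alpha/beta. Names are
#'   the group labels (e.g. `HC`, `PD_off`).
#' @param noise_1f_exponent Spectral slope of the background (PSD ~ 1/f^e).
#'   Default 1 (pink).
#' @param subject_gain_sd Log-scale sd of the per-subject, per-band lognormal
#'   gain (mean 1). Default 0.15.
#' @param informative_channels Indices of channels carrying the class effect;
#'   other channels use the first class's gains for everyone. Default: all.
#' @param background_sd Background noise sd in microvolts (default 1).
#' @param component_sd Per-band component sd at unit gain, microvolts
#'   (default 3).
#' @param seed RNG seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects_per_class = 10, ch = 8, fs = 256,
                           duration_s = 60,
                           class_band_gains = list(
                             HC = c(delta = 1, theta = 1, alpha = 1, beta = 1),
                             PD_off = c(delta = 1, theta = 1, alpha = 3,
                                        beta = 2)),
                           noise_1f_exponent = 1, subject_gain_sd = 0.15,
                           informative_channels = NULL, background_sd = 1,
                           component_sd = 3, seed = 1) {
  if (length(class_band_gains) != 2) {
    stop("exactly two classes required", call. = FALSE)
  }
  for (g in class_band_gains) {
    if (any(g <= 0) || !all(names(.synth_bands) %in% names(g))) {
      stop("each class needs positive gains named ",
           paste(names(.synth_bands), collapse = "/"), call. = FALSE)
    }
  }
  if (is.null(informative_channels)) informative_channels <- seq_len(ch)
  if (!all(informative_channels %in% seq_len(ch))) {
    stop("informative_channels out of range", call. = FALSE)
  }
  if (fs <= 2 * 30) stop("fs too low for the beta band", call. = FALSE)
  structure(list(n_subjects_per_class = n_subjects_per_class, ch = ch,
                 fs = fs, duration_s = duration_s,
                 class_band_gains = class_band_gains,
                 noise_1f_exponent = noise_1f_exponent,
                 subject_gain_sd = subject_gain_sd,
                 informative_channels = informative_channels,
                 background_sd = background_sd, component_sd = component_sd,
                 seed = seed),
            class = "synthetic_spec")
}

# 1/f^e noise via spectral shaping, unit sd
.pink_noise <- function(n, exponent) {
  nf <- n %/% 2
  f <- seq_len(nf)                       # frequency bin index
  amp <- f^(-exponent / 2)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  full[n:(n - nf + 2)] <- Conj(spec[seq_len(nf - 1)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / stats::sd(x)
}

# band-limited unit-sd noise: order-4 butterworth band-pass of white noise
.band_noise <- function(n, band, fs) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / stats::sd(x)
}

#' Generate a synthetic two-class cohort
#'
#' Deterministic given `spec$seed`. Subjects are labelled `<group>_s<i>`.
#'
#' @param spec A [synthetic_spec()].
#' @return List of [eeg_recording()]s, classes balanced and interleaved.
#' @export
generate_cohort <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- as.integer(spec$duration_s * spec$fs)
  groups <- names(spec$class_band_gains)
  base_gains <- spec$class_band_gains[[1]]
  recs <- list()
  for (g in groups) {
    for (s in seq_len(spec$n_subjects_per_class)) {
      sid <- sprintf("%s_s%02d", g, s)
      # one stable lognormal gain per band per subject, mean 1
      sgain <- stats::rlnorm(length(.synth_bands),
                             meanlog = -spec$subject_gain_sd^2 / 2,
                             sdlog = spec$subject_gain_sd)
      names(sgain) <- names(.synth_bands)
      data <- matrix(0, nrow = spec$ch, ncol = n)
      for (c_i in seq_len(spec$ch)) {
        gains <- if (c_i %in% spec$informative_channels) {
          spec$class_band_gains[[g]]
        } else base_gains
        x <- spec$background_sd * .pink_noise(n, spec$noise_1f_exponent)
        for (b in names(.synth_bands)) {
          x <- x + spec$component_sd * sqrt(gains[[b]] * sgain[[b]]) *
            .band_noise(n, .synth_bands[[b]], spec$fs)
        }
        data[c_i, ] <- x
      }
      recs[[sid]] <- eeg_recording(
        data, fs = spec$fs,
        channel_labels = paste0("ch", seq_len(spec$ch)),
        subject_id = sid,
        group = if (g %in% .groups) g else "HC")
    }
  }
  recs
}

#' Canonical synthetic benchmarks
#'
#' Fixed study conditions: 8 channels at 256 Hz, segmented at T = 2 s and
#' band-pass filtered (0.5-32 Hz). `easy` (2 x 10 subjects, 60 s each) plants
#' a 3x alpha / 2x beta power gain on all channels; `medium` (same cohort
#' shape) plants the gain on channels 2, 5, 7 only; `null` (2 x 20 subjects,
#' 30 s each) has no class difference.
#'
#' The null fixture also sets the subject-level gain variability to zero,
#' making segments exchangeable across subjects. With subject signatures
#' present, segment-level k-fold CV can exceed chance on label-free data by
#' recognising which subject a held-out segment came from (the intra-subject
#' leakage that motivates LOSO evaluation), which would defeat the fixture's
#' purpose as a permutation null.
#'
#' @param difficulty `"easy"`, `"medium"`, or `"null"`.
#' @param seed RNG seed.
#' @param T Segment length in seconds (default 2).
#' @return List with `segments` (a filtered `segment_set`), `labels` (group
#'   per segment), and `informative_channels` (indices, or `NULL` for null).
#' @export
make_separable_benchmark <- function(difficulty = c("easy", "medium", "null"),
                                     seed = 1, T = 2) {
  difficulty <- match.arg(difficulty)
  gains_pd <- switch(difficulty,
    easy = c(delta = 1, theta = 1, alpha = 3, beta = 2),
    medium = c(delta = 1, theta = 1, alpha = 3, beta = 2),
    null = c(delta = 1, theta = 1, alpha = 1, beta = 1))
  informative <- switch(difficulty,
    easy = 1:8, medium = c(2L, 5L, 7L), null = NULL)
  spec <- synthetic_spec(
    n_subjects_per_class = if (difficulty == "null") 20 else 10,
    ch = 8, fs = 256,
    duration_s = if (difficulty == "null") 30 else 60,
    class_band_gains = list(HC = c(delta = 1, theta = 1, alpha = 1, beta = 1),
                            PD_off = gains_pd),
    subject_gain_sd = if (difficulty == "null") 0 else 0.15,
    informative_channels = if (is.null(informative)) 1:8 else informative,
    seed = seed)
  recs <- generate_cohort(spec)
  fspec <- filter_spec()
  sets <- lapply(recs, function(r) {
    segment_recording(bandpass_filter(r, fspec), T)
  })
  segments <- bind_segment_sets(sets)
  labels <- vapply(segments, function(s) s$group, "")
  list(segments = segments, labels = labels,
       informative_channels = informative)
}
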