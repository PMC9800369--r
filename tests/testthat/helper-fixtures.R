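# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# benchmark (segments + LogEn feature matrix), cached by difficulty
bench_features <- function(difficulty, seed = 11) {
  key <- paste0(difficulty, "_", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  bm <- make_separable_benchmark(difficulty, seed = seed)
  fm <- build_feature_matrix(bm$segments, measure_spec("LogEn"))
  out <- list(fm = fm, labels = bm$labels,
              informative = bm$informative_channels)
  .fixture_cache[[key]] <- out
  out
}

# a single synthetic segment with the given channel count
make_segment <- function(ch = 4, n = 512, fs = 256, seed = 1,
                         group = "HC", subject = "S01") {
  set.seed(seed)
  structure(list(data = matrix(rnorm(ch * n), nrow = ch), fs = fs, T = n / fs,
                 channel_labels = paste0("ch", seq_len(ch)),
                 subject_id = subject, group = group, eye_state = "unknown",
                 segment_index = 1L),
            class = "eeg_segment")
}

# small feature matrix of well-separated 2-D clusters with subject structure
make_cluster_fm <- function(n_per_class = 50, gap = 10, seed = 5,
                            n_subjects = 5) {
  set.seed(seed)
  mk <- function(n, mu, lab) {
    data.frame(f1 = rnorm(n, mu), f2 = rnorm(n, mu), label = lab,
               subject = paste0(lab, "_s",
                                rep(seq_len(n_subjects), length.out = n)),
               stringsAsFactors = FALSE)
  }
  fm <- rbind(mk(n_per_class, 0, "HC"), mk(n_per_class, gap, "PD_off"))
  fm$label <- factor(fm$label)
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

# feature matrix with named channel blocks built directly from a matrix
make_block_fm <- function(m, labels, subjects, sources = "original") {
  df <- as.data.frame(m)
  df$label <- factor(labels)
  df$subject <- subjects
  class(df) <- c("feature_matrix", "data.frame")
  df
}
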