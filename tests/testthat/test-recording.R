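# Recording ingestion, segmentation, and band-pass preprocessing.

test_that("matrix + metadata loading populates the recording", {
  dir <- withr::local_tempdir()
  m <- matrix(rnorm(4 * 1000), nrow = 4)
  path <- file.path(dir, "rec.csv")
  write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(fs = 500, channel_labels = paste0("c", 1:4),
                            subject_id = "S07", group = "PD_off",
                            eye_state = "closed"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  rec <- load_recording(path, "matrix")
  expect_equal(nrow(rec$data), 4)
  expect_equal(ncol(rec$data), 1000)
  expect_equal(rec$fs, 500)
  expect_equal(rec$group, "PD_off")
  expect_equal(unname(rec$data[2, 7]), m[2, 7])

  # samples x channels orientation is detected from the label count
  path2 <- file.path(dir, "rec2.csv")
  write.table(t(m), path2, sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(fs = 500, channel_labels = paste0("c", 1:4)),
                       paste0(path2, ".json"), auto_unbox = TRUE)
  expect_message(rec2 <- load_recording(path2, "matrix"), "transposing")
  expect_equal(unname(rec2$data), m, tolerance = 1e-12)

  # NaN cells are a parse error
  m[1, 1] <- NaN
  write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_error(load_recording(path, "matrix"), "non-numeric|NA|non-finite")

  expect_error(load_recording(file.path(dir, "absent.csv"), "matrix"),
               "not found")
})

test_that("EDF files round-trip through the reader", {
  dir <- withr::local_tempdir()
  set.seed(42)
  fs <- 128
  data <- matrix(rnorm(3 * fs * 2, sd = 20), nrow = 3)
  path <- file.path(dir, "rec.edf")
  write_edf(path, data, fs, labels = c("Fz", "Cz", "Pz"), patient = "P9")
  rec <- load_recording(path, "edf")
  expect_equal(nrow(rec$data), 3)
  expect_equal(ncol(rec$data), fs * 2)
  expect_equal(rec$fs, fs)
  expect_equal(rec$channel_labels, c("Fz", "Cz", "Pz"))
  expect_equal(rec$subject_id, "P9")
  # values agree up to 16-bit quantization of the channel range
  expect_lt(max(abs(rec$data - data)), max(abs(data)) / 32767 * 1.01)
})

test_that("recording invariants are enforced", {
  expect_error(eeg_recording(matrix(1:4, 2), fs = -1), "fs")
  expect_error(eeg_recording(matrix(1:4, 2), fs = 100,
                             channel_labels = c("a", "a")), "unique")
  expect_error(eeg_recording(matrix(c(1, NA, 3, 4), 2), fs = 100), "NA")
  expect_error(eeg_recording(matrix(1:4, 2), fs = 100, group = "bad"))
})

test_that("segmentation emits floor(n / (T*fs)) whole windows", {
  rec <- eeg_recording(matrix(rnorm(2 * 60 * 500), nrow = 2), fs = 500)
  expect_length(segment_recording(rec, 2), 30)

  rec2 <- eeg_recording(matrix(rnorm(185 * 512), nrow = 1), fs = 512)
  expect_warning(segs <- segment_recording(rec2, 10), "discarding")
  expect_length(segs, 18)

  rec3 <- eeg_recording(matrix(rnorm(5 * 512), nrow = 1), fs = 512)
  expect_warning(segs3 <- segment_recording(rec3, 10), "shorter")
  expect_length(segs3, 0)

  expect_error(segment_recording(rec2, 0.0003), "whole number")
})

test_that("concatenated segments reproduce the leading samples exactly", {
  set.seed(3)
  rec <- eeg_recording(matrix(rnorm(3 * 1075), nrow = 3), fs = 100,
                       subject_id = "S1", group = "PD_on")
  suppressWarnings(segs <- segment_recording(rec, 2.5))
  expect_length(segs, 4)
  rebuilt <- do.call(cbind, lapply(segs, function(s) s$data))
  expect_identical(rebuilt, rec$data[, 1:1000])
  expect_equal(vapply(segs, function(s) s$segment_index, 0L), 1:4)
  expect_true(all(vapply(segs, function(s) s$group, "") == "PD_on"))
})

test_that("band-pass magnitude response has the designed pass and stop bands", {
  fsp <- filter_spec()
  h <- filter_response(fsp, 512, c(1e-4, 10, 100))
  expect_lt(h[1], 0.01)                 # DC blocked
  expect_equal(h[2], 1, tolerance = 0.05)  # 10 Hz passed
  expect_lt(h[3], 0.02)                 # 100 Hz stopped
  # half-power at the edges (magnitude 1/sqrt(2), squared by zero phase)
  expect_equal(filter_response(fsp, 512, c(0.5, 32)), c(0.5, 0.5),
               tolerance = 0.02)
})

test_that("filtering a tone and a constant matches the response in time", {
  fs <- 512
  t <- seq(1 / fs, 4, by = 1 / fs)
  mk <- function(v) {
    eeg_recording(rbind(v), fs = fs)
  }
  out10 <- bandpass_filter(mk(sin(2 * pi * 10 * t)))$data
  expect_equal(sqrt(mean(out10^2)) / sqrt(0.5), 1, tolerance = 0.05)
  outdc <- bandpass_filter(mk(rep(1, length(t))))$data
  expect_lt(sqrt(mean(outdc^2)), 0.01)
  # stop-band tone: steady-state portion, away from edge ringing
  t16 <- seq(1 / fs, 16, by = 1 / fs)
  out100 <- bandpass_filter(mk(sin(2 * pi * 100 * t16)))$data
  expect_lt(sqrt(mean(out100[(6 * fs):(10 * fs)]^2)) / sqrt(0.5), 0.02)
})

test_that("filtering is linear and channel-independent", {
  set.seed(9)
  fs <- 256
  x <- rnorm(1024)
  y <- rnorm(1024)
  f1 <- bandpass_filter(eeg_recording(rbind(x), fs = fs))$data
  f2 <- bandpass_filter(eeg_recording(rbind(y), fs = fs))$data
  fmix <- bandpass_filter(eeg_recording(rbind(2 * x + 3 * y), fs = fs))$data
  expect_lt(max(abs(fmix - (2 * f1 + 3 * f2))) / max(abs(fmix)), 1e-9)
  fboth <- bandpass_filter(eeg_recording(rbind(x, y), fs = fs))$data
  expect_equal(unname(fboth), unname(rbind(f1, f2)), tolerance = 1e-12)
})

test_that("invalid filter settings are rejected", {
  expect_error(filter_spec(low_hz = 5, high_hz = 2), "low_hz")
  rec <- eeg_recording(matrix(rnorm(200), 1), fs = 50)
  expect_error(bandpass_filter(rec, filter_spec(high_hz = 32)), "Nyquist")
})
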