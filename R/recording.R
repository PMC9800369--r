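# Recording / segment containers, ingestion, and band-pass preprocessing.

.groups <- c("PD_off", "PD_on", "HC")
.eye_states <- c("open", "closed", "unknown")

#' Multichannel EEG recording
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of unique channel names (10-20
#'   system), one per row of `data`.
#' @param subject_id Subject identifier.
#' @param group One of `"PD_off"`, `"PD_on"`, `"HC"`.
#' @param eye_state One of `"open"`, `"closed"`, `"unknown"`.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL,
                          subject_id = "S01", group = "HC",
                          eye_state = "unknown") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 1 || ncol(data) < 1) stop("empty data matrix", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data))) {
    stop("data contains NA or non-finite values", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("fs must be a positive scalar (Hz)", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("length(channel_labels) must equal the number of channels (rows)",
         call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  group <- match.arg(group, .groups)
  eye_state <- match.arg(eye_state, .eye_states)
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 subject_id = as.character(subject_id), group = group,
                 eye_state = eye_state),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s] %d ch x %d samples @ %g Hz (%.1f s), eyes %s\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs, x$eye_state))
  invisible(x)
}

#' Load an EEG recording from disk
#'
#' Two formats are supported: standard EDF (European Data Format, 16-bit), and
#' a delimited numeric matrix (CSV/TSV, channels x samples) with a JSON
#' metadata sidecar `{fs, channel_labels, subject_id, group, eye_state}` at
#' `<path>.json` (or given via `meta`).
#'
#' @param path File path.
#' @param format `"edf"` or `"matrix"`.
#' @param meta For `format = "matrix"`: path to the JSON sidecar; defaults to
#'   `paste0(path, ".json")`.
#' @return An [eeg_recording()].
#' @export
load_recording <- function(path, format = c("edf", "matrix"), meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edf") return(.read_edf(path))
  if (is.null(meta)) meta <- paste0(path, ".json")
  if (!file.exists(meta)) {
    stop("metadata sidecar not found: ", meta, call. = FALSE)
  }
  md <- jsonlite::fromJSON(meta)
  if (is.null(md$fs)) stop("metadata error: missing fs", call. = FALSE)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  if (!is.numeric(m) || anyNA(m)) {
    stop("parse error: non-numeric or missing cells in ", path, call. = FALSE)
  }
  labels <- md$channel_labels
  if (is.null(labels)) stop("metadata error: missing channel_labels",
                            call. = FALSE)
  # orientation heuristic: the dimension matching the label count is channels
  if (nrow(m) != length(labels) && ncol(m) == length(labels)) {
    message("transposing matrix input (detected samples x channels layout)")
    m <- t(m)
  }
  eeg_recording(m, fs = md$fs, channel_labels = labels,
                subject_id = if (is.null(md$subject_id)) "S01" else md$subject_id,
                group = if (is.null(md$group)) "HC" else md$group,
                eye_state = if (is.null(md$eye_state)) "unknown" else md$eye_state)
}

# minimal standard EDF reader (16-bit little-endian samples)
.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchar) trimws(rawToChar(readBin(con, "raw", nchar)))
  rd(8)                       # version
  pat <- rd(80)               # patient id
  rd(80)                      # recording id
  rd(8); rd(8)                # start date/time
  as.numeric(rd(8))           # header bytes
  rd(44)                      # reserved
  n_records <- as.numeric(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.numeric(rd(4))
  if (is.na(ns) || ns < 1) stop("EDF header error: bad signal count",
                                call. = FALSE)
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  vapply(seq_len(ns), function(i) rd(80), "")   # transducer
  vapply(seq_len(ns), function(i) rd(8), "")    # physical dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")   # prefiltering
  nsamp <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")   # reserved
  if (anyNA(c(pmin_, pmax_, dmin_, dmax_, nsamp, n_records, record_dur))) {
    stop("EDF header error: unparseable numeric field", call. = FALSE)
  }
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  offset <- pmin_ - gain * dmin_
  data <- matrix(0, nrow = ns, ncol = nsamp[1] * n_records)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nsamp[s], size = 2, signed = TRUE,
                     endian = "little")
      data[s, ((r - 1) * nsamp[s] + 1):(r * nsamp[s])] <-
        gain[s] * dig + offset[s]
    }
  }
  fs <- nsamp[1] / record_dur
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  eeg_recording(data, fs = fs, channel_labels = labels,
                subject_id = if (nzchar(pat)) strsplit(pat, " ")[[1]][1] else "S01")
}

#' Cut a recording into fixed-length non-overlapping segments
#'
#' @param rec An [eeg_recording()].
#' @param T Window length in seconds; `T * fs` must be a whole number of
#'   samples.
#' @return Object of class `segment_set`: a list of `eeg_segment`s, each a
#'   channels x (T*fs) matrix with provenance (`subject_id`, `group`,
#'   `segment_index`) and `fs`, `T`, `channel_labels`, `eye_state` carried
#'   through. A trailing partial window is discarded with a warning.
#' @export
segment_recording <- function(rec, T) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(T) || length(T) != 1 || T <= 0) {
    stop("T must be a positive scalar (seconds)", call. = FALSE)
  }
  win <- T * rec$fs
  if (abs(win - round(win)) > 1e-9) {
    stop("T * fs = ", win, " is not a whole number of samples", call. = FALSE)
  }
  win <- as.integer(round(win))
  n <- ncol(rec$data)
  k <- n %/% win
  leftover <- n - k * win
  if (k == 0) {
    warning("recording shorter than one window (", n, " < ", win,
            " samples); no segments emitted")
    return(structure(list(), class = "segment_set"))
  }
  if (leftover > 0) {
    warning("discarding trailing partial window (", leftover, " samples, ",
            signif(leftover / rec$fs, 4), " s)")
  }
  segs <- lapply(seq_len(k), function(i) {
    structure(list(
      data = rec$data[, ((i - 1) * win + 1):(i * win), drop = FALSE],
      fs = rec$fs, T = T, channel_labels = rec$channel_labels,
      subject_id = rec$subject_id, group = rec$group,
      eye_state = rec$eye_state, segment_index = i
    ), class = "eeg_segment")
  })
  structure(segs, class = "segment_set")
}

#' Combine segment sets
#'
#' @param ... `segment_set` objects.
#' @return A single `segment_set`.
#' @export
bind_segment_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "segment_set")) {
    sets <- sets[[1]]
  }
  stopifnot(all(vapply(sets, inherits, TRUE, "segment_set")))
  structure(do.call(c, lapply(sets, unclass)), class = "segment_set")
}

#' Band-pass filter specification
#'
#' @param low_hz Lower passband edge (default 0.5 Hz).
#' @param high_hz Upper passband edge (default 32 Hz).
#' @param order Butterworth order (default 5). With zero-phase application the
#'   effective magnitude order doubles.
#' @param zero_phase Apply forward-backward (`signal::filtfilt`), default
#'   `TRUE`; avoids group-delay distortion of segment-local features.
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.5, high_hz = 32, order = 5,
                        zero_phase = TRUE) {
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  }
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 kind = "butterworth_bandpass", zero_phase = zero_phase),
            class = "filter_spec")
}

# Band-pass Butterworth as second-order sections (biquad cascade).
# The single transfer-function form of an order-5 band-pass with a 0.5 Hz
# lower edge is numerically unstable at EEG sampling rates (a pole crosses the
# unit circle under coefficient rounding), so the filter is designed from the
# analog prototype and factored into biquads: prototype poles -> band
# transform -> bilinear transform -> conjugate pairing, with one zero at z = 1
# and one at z = -1 per section and unit gain at the band's geometric centre.
.butter_bp_sos <- function(spec, fs) {
  if (spec$high_hz >= fs / 2) {
    stop("high_hz (", spec$high_hz, ") must be below the Nyquist rate fs/2 = ",
         fs / 2, call. = FALSE)
  }
  n <- spec$order
  # analog low-pass prototype poles (Butterworth, left half-plane)
  k <- seq_len(n)
  pp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # pre-warped band edges
  w1 <- 2 * fs * tan(pi * spec$low_hz / fs)
  w2 <- 2 * fs * tan(pi * spec$high_hz / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # low-pass -> band-pass: each prototype pole p yields the roots of
  # s^2 - p*bw*s + w0^2
  poles <- c()
  for (p in pp) {
    disc <- sqrt((p * bw / 2)^2 - w0^2)
    poles <- c(poles, p * bw / 2 + disc, p * bw / 2 - disc)
  }
  # bilinear transform
  zp <- (2 * fs + poles) / (2 * fs - poles)
  # group into sections: conjugate pairs, then leftover real poles in pairs
  tol <- 1e-8
  cplx <- zp[Im(zp) > tol]
  realp <- Re(zp[abs(Im(zp)) <= tol])
  sections <- list()
  for (p in cplx) {
    sections[[length(sections) + 1]] <-
      list(b = c(1, 0, -1), a = c(1, -2 * Re(p), Mod(p)^2))
  }
  realp <- sort(realp)
  while (length(realp) >= 2) {
    p1 <- realp[1]; p2 <- realp[length(realp)]
    realp <- realp[-c(1, length(realp))]
    sections[[length(sections) + 1]] <-
      list(b = c(1, 0, -1), a = c(1, -(p1 + p2), p1 * p2))
  }
  # unit gain at the geometric centre frequency
  wc <- 2 * pi * sqrt(spec$low_hz * spec$high_hz) / fs
  z <- exp(1i * wc)
  h <- prod(vapply(sections, function(s) {
    Mod(sum(s$b * z^(0:-2)) / sum(s$a * z^(0:-2)))
  }, 0))
  g <- h^(-1 / length(sections))
  lapply(sections, function(s) { s$b <- s$b * g; s })
}

# complex frequency response of a biquad cascade at frequencies f (Hz)
.sos_response <- function(sos, f, fs) {
  z <- exp(1i * 2 * pi * f / fs)
  out <- rep(1 + 0i, length(z))
  for (s in sos) {
    out <- out * (s$b[1] + s$b[2] / z + s$b[3] / z^2) /
      (s$a[1] + s$a[2] / z + s$a[3] / z^2)
  }
  out
}

#' Magnitude response of the band-pass preprocessing filter
#'
#' Returns the effective magnitude (squared when `zero_phase`, since the
#' filter is applied forward and backward) at the requested frequencies.
#'
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz.
#' @param f Frequencies (Hz) at which to evaluate.
#' @return Numeric vector of magnitudes.
#' @export
filter_response <- function(spec, fs, f) {
  h <- Mod(.sos_response(.butter_bp_sos(spec, fs), f, fs))
  if (spec$zero_phase) h^2 else h
}

# steady-state initial conditions of the direct-form-II-transposed filter
# (step input produces an immediately steady output)
.lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, numeric(nf - length(b)))
  a <- c(a, numeric(nf - length(a)))
  n <- nf - 1
  # companion matrix of a (a[1] == 1)
  comp <- matrix(0, n, n)
  comp[1, ] <- -a[-1]
  if (n > 1) comp[cbind(2:n, 1:(n - 1))] <- 1
  B <- b[-1] - a[-1] * b[1]
  M <- diag(n) - t(comp)
  # narrow low edges put a pole near z = 1, making M near-singular; an
  # approximate state still cancels the start-up transient, so solve by QR
  # with no condition cutoff
  qr.solve(M, B, tol = .Machine$double.xmin)
}

# direct-form-II-transposed IIR filter with initial state
.df2t <- function(b, a, x, zi) {
  nf <- max(length(a), length(b))
  b <- c(b, numeric(nf - length(b)))
  a <- c(a, numeric(nf - length(a)))
  z <- zi
  y <- numeric(length(x))
  jj <- seq_len(nf - 2)
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    z[jj] <- b[jj + 1] * xi + z[jj + 1] - a[jj + 1] * yi
    z[nf - 1] <- b[nf] * xi - a[nf] * yi
    y[i] <- yi
  }
  y
}

# run the whole biquad cascade once, with steady-state initial conditions
# scaled to the first sample (scipy sosfilt + sosfilt_zi semantics; the
# cumulative scale is each preceding section's DC gain)
.sosfilt <- function(sos, x, x0 = 0) {
  scale <- 1
  for (s in sos) {
    zi <- .lfilter_zi(s$b, s$a) * scale * x0
    x <- .df2t(s$b, s$a, x, zi)
    scale <- scale * sum(s$b) / sum(s$a)
  }
  x
}

# zero-phase forward-backward cascade filtering with odd-reflection padding
# (the standard offline-EEG filtfilt)
.sosfiltfilt <- function(sos, x) {
  n <- length(x)
  n_ext <- min(3 * (2 * length(sos) + 1), n - 1)
  left <- 2 * x[1] - x[(n_ext + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - n_ext)]
  ext <- c(left, x, right)
  y <- .sosfilt(sos, ext, x0 = ext[1])
  y <- rev(.sosfilt(sos, rev(y), x0 = y[length(y)]))
  y[(n_ext + 1):(n_ext + n)]
}

.filter_matrix <- function(m, spec, fs) {
  sos <- .butter_bp_sos(spec, fs)
  out <- m
  for (i in seq_len(nrow(m))) {
    out[i, ] <- if (spec$zero_phase) {
      .sosfiltfilt(sos, m[i, ])
    } else {
      x <- m[i, ]
      for (s in sos) x <- as.numeric(signal::filter(s$b, s$a, x))
      x
    }
  }
  out
}

#' Band-pass filter a segment, recording, or segment set
#'
#' Each channel is filtered independently; output has the same shape.
#'
#' @param x An `eeg_segment`, `eeg_recording`, or `segment_set`.
#' @param spec A [filter_spec()].
#' @return Same type as `x`.
#' @export
bandpass_filter <- function(x, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  UseMethod("bandpass_filter")
}

#' @export
bandpass_filter.eeg_segment <- function(x, spec = filter_spec()) {
  x$data <- .filter_matrix(x$data, spec, x$fs)
  x
}

#' @export
bandpass_filter.eeg_recording <- function(x, spec = filter_spec()) {
  x$data <- .filter_matrix(x$data, spec, x$fs)
  x
}

#' @export
bandpass_filter.segment_set <- function(x, spec = filter_spec()) {
  structure(lapply(unclass(x), bandpass_filter, spec = spec),
            class = "segment_set")
}
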