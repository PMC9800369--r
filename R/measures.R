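# Signal complexity measures used as per-sub-band features.
#
# Two evaluation modes are exposed via measure_spec(value_mode=):
#   "sample"      — x_i ranges over the raw samples and k = N. This is how
#                   MATLAB's wentropy-style measures behave on continuous
#                   signals, and is the default for ThEn/NoEn/SuEn/LogEn/ShEn
#                   (on continuous data every sample is unique, so a
#                   unique-value histogram would be degenerate).
#   "unique_prob" — x_i ranges over the relative frequencies of the k unique
#                   values. Default for TShEn only, whose 0..255 quantized
#                   input makes unique-value frequencies well defined.
# Conventions: natural log; log(0) and 0*log(0) terms contribute 0.

.measure_names <- c("Eng", "LBP", "ThEn", "NoEn", "SuEn", "LogEn", "ShEn",
                    "TShEn")

#' Feature measure settings
#'
#' @param name One of `"Eng"`, `"LBP"`, `"ThEn"`, `"NoEn"`, `"SuEn"`,
#'   `"LogEn"`, `"ShEn"`, `"TShEn"`.
#' @param alpha Threshold for ThEn; must be in (0, 1). Default 0.2.
#' @param p Norm power for NoEn; must be >= 1. Default 1.1.
#' @param pound Sure-entropy threshold; must exceed 2. Default 3.
#' @param t_min,t_max Intensity-transform output range for TShEn. Default
#'   0..255 (8-bit image intensities).
#' @param value_mode `"sample"` or `"unique_prob"`; `NULL` picks the default
#'   for the measure (`"unique_prob"` for TShEn, `"sample"` otherwise).
#' @param quantize Round the transformed signal to integers (TShEn). Default
#'   `TRUE`.
#' @param negate_shannon Use the conventional negated Shannon form instead of
#'   the plain sum. Default `FALSE` (as printed).
#' @return Object of class `measure_spec`.
#' @export
measure_spec <- function(name = "LogEn", alpha = 0.2, p = 1.1, pound = 3,
                         t_min = 0, t_max = 255, value_mode = NULL,
                         quantize = TRUE, negate_shannon = FALSE) {
  name <- match.arg(name, .measure_names)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  if (p < 1) stop("norm power p must be >= 1", call. = FALSE)
  if (pound <= 2) stop("sure threshold must exceed 2", call. = FALSE)
  if (t_min >= t_max) stop("t_min must be below t_max", call. = FALSE)
  if (is.null(value_mode)) {
    value_mode <- if (name == "TShEn") "unique_prob" else "sample"
  }
  value_mode <- match.arg(value_mode, c("sample", "unique_prob"))
  structure(list(name = name, alpha = alpha, p = p, pound = pound,
                 t_min = t_min, t_max = t_max, value_mode = value_mode,
                 quantize = quantize, negate_shannon = negate_shannon),
            class = "measure_spec")
}

# values the entropy sum ranges over, per mode
.measure_values <- function(x, value_mode) {
  if (value_mode == "sample") return(x)
  as.numeric(table(x)) / length(x)
}

#' Signal energy (sum of squared amplitudes)
#' @param x Numeric vector.
#' @return Scalar `sum(|x|^2)`.
#' @export
energy <- function(x) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  sum(abs(x)^2)
}

#' Log band power (natural log of mean squared amplitude)
#' @param x Numeric vector; must not be all zero.
#' @return Scalar `log(mean(|x|^2))`.
#' @export
log_band_power <- function(x) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  ms <- mean(abs(x)^2)
  if (ms == 0) stop("degenerate input: all-zero signal has no band power",
                    call. = FALSE)
  log(ms)
}

#' Threshold entropy: count of values exceeding a threshold in magnitude
#' @param x Numeric vector.
#' @param spec A [measure_spec()]; uses `alpha` (strict `>` comparison) and
#'   `value_mode`.
#' @return Integer count.
#' @export
threshold_entropy <- function(x, spec = measure_spec("ThEn")) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  v <- .measure_values(x, spec$value_mode)
  sum(abs(v) > spec$alpha)
}

#' Norm entropy: sum of magnitudes to the power p
#' @inheritParams threshold_entropy
#' @return Scalar `sum(|x_i|^p)`.
#' @export
norm_entropy <- function(x, spec = measure_spec("NoEn")) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  v <- .measure_values(x, spec$value_mode)
  sum(abs(v)^spec$p)
}

#' Sure entropy
#'
#' `k - #\{i : |x_i| <= t\} + sum(min(x_i^2, t^2))` with threshold `t` from
#' `spec$pound`, `k` the number of values summed over.
#' @inheritParams threshold_entropy
#' @return Scalar.
#' @export
sure_entropy <- function(x, spec = measure_spec("SuEn")) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  v <- .measure_values(x, spec$value_mode)
  t <- spec$pound
  length(v) - sum(abs(v) <= t) + sum(pmin(v^2, t^2))
}

#' Log energy entropy: sum of log squared magnitudes (zero terms contribute 0)
#' @inheritParams threshold_entropy
#' @return Scalar.
#' @export
log_energy_entropy <- function(x, spec = measure_spec("LogEn")) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  v <- .measure_values(x, spec$value_mode)
  nz <- v != 0
  sum(log(v[nz]^2))
}

#' Shannon entropy (as-printed form, no leading minus)
#'
#' `sum(|x_i|^2 * log(|x_i|^2))`, zero terms contributing 0. Set
#' `negate_shannon = TRUE` in the spec for the conventional negated form.
#' @inheritParams threshold_entropy
#' @return Scalar.
#' @export
shannon_entropy <- function(x, spec = measure_spec("ShEn")) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  v <- .measure_values(x, spec$value_mode)
  nz <- v != 0
  s <- sum(v[nz]^2 * log(v[nz]^2))
  if (spec$negate_shannon) -s else s
}

#' Image-style intensity transform of a signal
#'
#' Clips and rescales each sample: values above 1 map to `t_max`, values below
#' 0 map to `t_min`, and values in `[0, 1]` map linearly to
#' `t_max * x + t_min`; then (by default) rounds half-up to integers,
#' emulating 8-bit image intensities. The mapping bounds the signal to
#' `[t_min, t_max]` and sharply reduces the number of unique values.
#'
#' @param x Numeric vector.
#' @param spec A [measure_spec()]; uses `t_min`, `t_max`, `quantize`.
#' @return Numeric vector, same length as `x`, values in `[t_min, t_max]`.
#' @export
intensity_transform <- function(x, spec = measure_spec("TShEn")) {
  y <- ifelse(x > 1, spec$t_max,
              ifelse(x < 0, spec$t_min, spec$t_max * x + spec$t_min))
  if (spec$quantize) y <- floor(y + 0.5)   # round half up
  y
}

#' Transformation-Shannon entropy (TShEn)
#'
#' Applies [intensity_transform()] then the normalized Shannon form
#' `(1/k) * sum(p_i^2 * log(p_i^2))` over the `k` unique quantized values with
#' relative frequencies `p_i` (default `value_mode = "unique_prob"`).
#'
#' @inheritParams threshold_entropy
#' @return Scalar.
#' @export
t_shannon_entropy <- function(x, spec = measure_spec("TShEn")) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  tr <- intensity_transform(x, spec)
  v <- .measure_values(tr, spec$value_mode)
  nz <- v != 0
  s <- sum(v[nz]^2 * log(v[nz]^2)) / length(v)
  if (spec$negate_shannon) -s else s
}

# dispatch a measure by spec
.apply_measure <- function(x, spec) {
  switch(spec$name,
         Eng = energy(x),
         LBP = log_band_power(x),
         ThEn = threshold_entropy(x, spec),
         NoEn = norm_entropy(x, spec),
         SuEn = sure_entropy(x, spec),
         LogEn = log_energy_entropy(x, spec),
         ShEn = shannon_entropy(x, spec),
         TShEn = t_shannon_entropy(x, spec))
}
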