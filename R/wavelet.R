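# Discrete wavelet transform: decomposition and per-coefficient reconstruction.
#
# Plain DWT tree (only approximations are split). The symmetric (half-point)
# boundary mode is used, under which coefficient lengths follow
# len_j = floor((len_{j-1} + filter_len - 1) / 2).

# Scaling (dec_lo) filters of common orthogonal wavelets, standard published
# values, ordered as in the usual convolution convention.
.wavelet_filters <- list(
  db1 = c(0.70710678118654757, 0.70710678118654757),
  db2 = c(-0.12940952255126037, 0.22414386804201339, 0.83651630373780794,
          0.48296291314453416),
  db3 = c(0.035226291885709533, -0.085441273882026658, -0.13501102001025458,
          0.45987750211849154, 0.80689150931109255, 0.33267055295008263),
  db4 = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
          0.71484657055291567, 0.23037781330889651),
  db5 = c(0.0033357252854737712, -0.012580751999081999, -0.0062414902127982744,
          0.077571493840045719, -0.032244869584638375, -0.24229488706638203,
          0.13842814590132074, 0.72430852843777294, 0.60382926979718965,
          0.16010239797419293),
  db6 = c(-0.0010773010853084796, 0.0047772575109455108, 0.00055384220116149613,
          -0.03158203931748603, 0.027522865530305727, 0.097501605587323043,
          -0.12976686756726194, -0.22626469396543983, 0.31525035170919763,
          0.75113390802109536, 0.49462389039845306, 0.11154074335010947),
  db7 = c(0.00035371379997452024, -0.0018016407040474908, 0.00042957797292136651,
          0.01255099855609984, -0.016574541630666881, -0.038029936935014413,
          0.080612609151083078, 0.071309219266830259, -0.22403618499387498,
          -0.14390600392856498, 0.46978228740519312, 0.72913209084623509,
          0.39653931948191729, 0.077852054085009184),
  db8 = c(-0.00011747678412476953, 0.00067544940645056933, -0.00039174037337694705,
          -0.0048703529934515741, 0.0087460940474057766, 0.013981027917398282,
          -0.044088253930794755, -0.017369301001807547, 0.12874742662047847,
          0.00047248457391328279, -0.28401554296154691, -0.015829105256349306,
          0.58535468365420673, 0.67563073629728976, 0.31287159091429995,
          0.054415842243104008),
  sym4 = c(-0.075765714789273325, -0.02963552764599851, 0.49761866763201545,
           0.80373875180591614, 0.29785779560527736, -0.099219543576847216,
           -0.012603967262037833, 0.032223100604042702),
  sym5 = c(0.027333068345077982, 0.029519490925774643, -0.039134249302383094,
           0.1993975339773936, 0.72340769040242059, 0.63397896345821192,
           0.016602105764522319, -0.17532808990845047, -0.021101834024758855,
           0.019538882735286728),
  sym8 = c(-0.0033824159510061256, -0.00054213233179114812, 0.031695087811492981,
           0.0076074873249176054, -0.14329423835080971, -0.061273359067658524,
           0.48135965125837221, 0.77718575170052351, 0.3644418948353314,
           -0.051945838107709037, -0.027219029917056003, 0.049137179673607506,
           0.0038087520138906151, -0.014952258337048231, -0.0003029205147213668,
           0.0018899503327594609),
  coif1 = c(-0.015655728135791993, -0.07273261951252645, 0.38486484686485778,
            0.85257202021160039, 0.33789766245748182, -0.07273261951252645),
  coif2 = c(-0.00072054944552034698, -0.0018232088709110323, 0.0056114348193688343,
            0.02368017194684777, -0.059434418646431092, -0.076488599078280761,
            0.41700518442323908, 0.81272363544941351, 0.38611006682276289,
            -0.067372554723725595, -0.041464936786871777, 0.016387336463203641),
  coif3 = c(-3.4599773197272781e-05, -7.0983302506379004e-05, 0.00046621695982040288,
            0.0011175187708306303, -0.0025745176881367972, -0.0090079761367306242,
            0.015880544863669452, 0.034555027573297738, -0.082301927106299827,
            -0.071799821619154838, 0.42848347637737, 0.79377722262608719,
            0.40517690240911824, -0.061123390002972552, -0.065771911281469364,
            0.023452696142077168, 0.0077825964256727463, -0.0037935128643808019)
)

.wavelet_bank <- function(mother) {
  dec_lo <- .wavelet_filters[[mother]]
  if (is.null(dec_lo)) {
    stop("unknown wavelet '", mother, "'; available: ",
         paste(names(.wavelet_filters), collapse = ", "), call. = FALSE)
  }
  f <- length(dec_lo)
  dec_hi <- rev(dec_lo) * (-1)^seq_len(f)   # quadrature mirror
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi), len = f)
}

#' Wavelet decomposition settings
#'
#' @param mother Mother wavelet name. Default `"db4"` (Daubechies-4, 8-tap),
#'   the standard choice for EEG sub-band analysis.
#' @param level Decomposition depth; default 4, which at fs = 512 Hz yields the
#'   0-16 / 16-32 / 32-64 / 64-128 / 128-256 Hz sub-band structure.
#' @param boundary Signal extension mode at the edges. Only `"symmetric"`
#'   (half-point, edge sample repeated) is implemented; it is the common
#'   default of MATLAB's `wavedec` tool chain.
#' @return An object of class `wavelet_spec`.
#' @export
wavelet_spec <- function(mother = "db4", level = 4, boundary = "symmetric") {
  if (!is.numeric(level) || level < 1 || level != round(level)) {
    stop("level must be a positive integer", call. = FALSE)
  }
  boundary <- match.arg(boundary, "symmetric")
  .wavelet_bank(mother)  # validates the name
  structure(list(mother = mother, level = as.integer(level),
                 boundary = boundary),
            class = "wavelet_spec")
}

# single-level analysis step, symmetric half-point extension
.dwt_step <- function(x, bank) {
  f <- bank$len
  n <- length(x)
  # half-point symmetric extension: ... x2 x1 | x1 x2 ... xn | xn x(n-1) ...
  left <- rev(x[seq_len(min(f - 1, n))])
  right <- rev(x)[seq_len(min(f - 1, n))]
  while (length(left) < f - 1) left <- c(rev(left), left)[seq_len(f - 1)]
  while (length(right) < f - 1) right <- c(right, rev(right))[seq_len(f - 1)]
  ext <- c(left, x, right)
  outlen <- (n + f - 1) %/% 2
  idx <- f + 1 + 2 * (seq_len(outlen) - 1)
  list(a = stats::convolve(ext, rev(bank$dec_lo), type = "open")[idx],
       d = stats::convolve(ext, rev(bank$dec_hi), type = "open")[idx])
}

# single-level synthesis step: upsample, filter, trim f-2 from each side,
# then truncate to the target length
.idwt_step <- function(a, d, bank, target_len) {
  f <- bank$len
  up <- function(v) {
    o <- numeric(2L * length(v) - 1L)
    o[seq(1L, length(o), 2L)] <- v
    o
  }
  full <- stats::convolve(up(a), rev(bank$rec_lo), type = "open") +
    stats::convolve(up(d), rev(bank$rec_hi), type = "open")
  y <- full[(f - 1):(length(full) - f + 2)]
  y[seq_len(target_len)]
}

#' Multi-level DWT decomposition
#'
#' Decomposes a single-channel signal into an approximation coefficient vector
#' at the deepest level plus one detail vector per level (the plain DWT tree:
#' only approximations are split).
#'
#' @param x Numeric vector, length at least `2^level`.
#' @param spec A [wavelet_spec()].
#' @return An object of class `wavelet_coeffs` with elements `cA` (deepest
#'   approximation), `cD` (list, `cD[[j]]` = level-j details), `lengths`
#'   (input length at each level, used by reconstruction), `spec`, and
#'   `n_original`.
#' @export
dwt_decompose <- function(x, spec = wavelet_spec()) {
  stopifnot(inherits(spec, "wavelet_spec"))
  x <- as.numeric(x)
  if (anyNA(x)) stop("signal contains NA", call. = FALSE)
  minlen <- 2^spec$level
  if (length(x) < minlen) {
    stop("signal of length ", length(x), " too short for a level-", spec$level,
         " decomposition; at least ", minlen, " samples required",
         call. = FALSE)
  }
  bank <- .wavelet_bank(spec$mother)
  cD <- vector("list", spec$level)
  lengths <- integer(spec$level)
  a <- x
  for (j in seq_len(spec$level)) {
    lengths[j] <- length(a)
    st <- .dwt_step(a, bank)
    cD[[j]] <- st$d
    a <- st$a
  }
  structure(list(cA = a, cD = cD, lengths = lengths, spec = spec,
                 n_original = length(x)),
            class = "wavelet_coeffs")
}

#' Full inverse DWT
#'
#' @param coeffs A `wavelet_coeffs` object from [dwt_decompose()].
#' @return Numeric vector of length `coeffs$n_original`.
#' @export
dwt_reconstruct <- function(coeffs) {
  stopifnot(inherits(coeffs, "wavelet_coeffs"))
  bank <- .wavelet_bank(coeffs$spec$mother)
  a <- coeffs$cA
  for (j in rev(seq_len(coeffs$spec$level))) {
    a <- .idwt_step(a, coeffs$cD[[j]], bank, coeffs$lengths[j])
  }
  a
}

#' Reconstruct one full-length signal per coefficient set
#'
#' Inverts the transform once per coefficient set with every other set zeroed,
#' producing `level + 1` band-limited signals each at the original length
#' ("WP signals": cA_L plus cD_L .. cD_1). Their element-wise sum equals the
#' original signal up to floating-point error.
#'
#' @param coeffs A `wavelet_coeffs` object.
#' @param fs Optional sampling rate in Hz; when given, nominal band edges are
#'   attached (see [band_edges()]).
#' @return An object of class `wp_signal_set`: a named list of signals in the
#'   order cA4, cD4, ..., cD1 (for level 4), with attribute `band_edges_hz`.
#' @export
wp_signals <- function(coeffs, fs = NULL) {
  stopifnot(inherits(coeffs, "wavelet_coeffs"))
  L <- coeffs$spec$level
  zero <- function(v) numeric(length(v))
  sets <- vector("list", L + 1)
  names(sets) <- c(paste0("cA", L), paste0("cD", rev(seq_len(L))))
  # cA-only
  only <- coeffs
  only$cD <- lapply(coeffs$cD, zero)
  sets[[paste0("cA", L)]] <- dwt_reconstruct(only)
  for (j in seq_len(L)) {
    only <- coeffs
    only$cA <- zero(coeffs$cA)
    only$cD <- lapply(coeffs$cD, zero)
    only$cD[[j]] <- coeffs$cD[[j]]
    sets[[paste0("cD", j)]] <- dwt_reconstruct(only)
  }
  edges <- if (!is.null(fs)) band_edges(fs, L) else NULL
  structure(sets, band_edges_hz = edges, class = "wp_signal_set")
}

#' Nominal sub-band edges of a level-L DWT
#'
#' The deepest approximation cA_L covers (0, fs/2^(L+1)); the level-j details
#' cD_j cover (fs/2^(j+1), fs/2^j). At fs = 512 Hz and L = 4 this is the
#' familiar 0-16, 16-32, 32-64, 64-128, 128-256 Hz ladder.
#'
#' @param fs Sampling rate in Hz.
#' @param level Decomposition depth.
#' @return Data frame with columns `signal`, `low_hz`, `high_hz`, ordered
#'   cA_L, cD_L, ..., cD_1.
#' @export
band_edges <- function(fs, level) {
  stopifnot(fs > 0, level >= 1)
  sig <- c(paste0("cA", level), paste0("cD", rev(seq_len(level))))
  low <- c(0, fs / 2^(rev(seq_len(level)) + 1))
  high <- c(fs / 2^(level + 1), fs / 2^rev(seq_len(level)))
  data.frame(signal = sig, low_hz = low, high_hz = high,
             stringsAsFactors = FALSE)
}

#' Coefficient lengths under the dyadic recursion
#'
#' @param n Input length.
#' @param spec A [wavelet_spec()].
#' @return Integer vector, one coefficient length per level (level 1 first).
#' @export
dwt_coeff_lengths <- function(n, spec = wavelet_spec()) {
  f <- .wavelet_bank(spec$mother)$len
  out <- integer(spec$level)
  len <- n
  for (j in seq_len(spec$level)) {
    len <- (len + f - 1) %/% 2
    out[j] <- len
  }
  out
}
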