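# Assembly of per-segment feature vectors and the feature matrix.
#
# Layout is channel-major: for each channel in order, one feature per source
# in the order original, cA4, cD4, cD3, cD2, cD1 (for level 4). Default mode
# computes the measure on the five reconstructed sub-band signals plus the raw
# segment: 6 features per channel.

.source_order <- function(level) {
  c("original", paste0("cA", level), paste0("cD", rev(seq_len(level))))
}

#' Extract the feature vector of one segment
#'
#' @param seg An `eeg_segment` (already band-pass filtered).
#' @param measure A [measure_spec()].
#' @param wspec A [wavelet_spec()].
#' @param use_dwt One of `"decompose_reconstruct"` (default: measure on each
#'   of the reconstructed sub-band signals plus the raw segment),
#'   `"decompose_only"` (measure on the raw coefficient vectors plus the raw
#'   segment), `"none"` (one feature per channel, from the raw segment).
#' @return Named numeric vector; length `6 * ch` in the DWT modes (`level + 2`
#'   sources per channel for a level-4 transform), `ch` in mode `"none"`.
#'   Names are `<channel>.<source>`. Attributes `label` and `subject_id`
#'   carry the segment provenance.
#' @export
extract_segment_features <- function(seg, measure = measure_spec(),
                                     wspec = wavelet_spec(),
                                     use_dwt = c("decompose_reconstruct",
                                                 "decompose_only", "none")) {
  stopifnot(inherits(seg, "eeg_segment"))
  use_dwt <- match.arg(use_dwt)
  ch <- nrow(seg$data)
  vals <- list()
  for (i in seq_len(ch)) {
    x <- seg$data[i, ]
    lab <- seg$channel_labels[i]
    res <- tryCatch({
      if (use_dwt == "none") {
        v <- c(original = .apply_measure(x, measure))
      } else {
        cf <- dwt_decompose(x, wspec)
        sources <- if (use_dwt == "decompose_reconstruct") {
          wp_signals(cf, fs = seg$fs)
        } else {
          sets <- c(list(cf$cA), rev(cf$cD))
          names(sets) <- .source_order(wspec$level)[-1]
          sets
        }
        v <- c(.apply_measure(x, measure),
               vapply(sources, .apply_measure, 0, spec = measure))
        names(v)[1] <- "original"
        v
      }
    }, error = function(e) {
      stop("feature extraction failed at channel '", lab, "': ",
           conditionMessage(e), call. = FALSE)
    })
    names(res) <- paste(lab, names(res), sep = ".")
    vals[[i]] <- res
  }
  out <- unlist(vals)
  structure(out, label = seg$group, subject_id = seg$subject_id)
}

#' Build the feature matrix of a segment set
#'
#' One row per segment, in the order of the set, with group label and subject
#' id carried through.
#'
#' @param segments A `segment_set`.
#' @inheritParams extract_segment_features
#' @return A data frame of class `feature_matrix`: feature columns followed by
#'   factor column `label` and character column `subject`.
#' @export
build_feature_matrix <- function(segments, measure = measure_spec(),
                                 wspec = wavelet_spec(),
                                 use_dwt = "decompose_reconstruct") {
  stopifnot(inherits(segments, "segment_set"))
  if (length(segments) == 0) stop("empty segment set", call. = FALSE)
  rows <- lapply(seq_along(segments), function(i) {
    v <- extract_segment_features(segments[[i]], measure, wspec, use_dwt)
    if (any(!is.finite(v))) {
      bad <- names(v)[!is.finite(v)][1]
      stop("non-finite feature value in segment ", i, " at ", bad,
           call. = FALSE)
    }
    v
  })
  m <- do.call(rbind, rows)
  df <- as.data.frame(m)
  df$label <- factor(vapply(segments, function(s) s$group, ""))
  df$subject <- vapply(segments, function(s) s$subject_id, "")
  class(df) <- c("feature_matrix", "data.frame")
  df
}

#' Feature columns of a feature matrix
#' @param fm A `feature_matrix`.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(fm) {
  setdiff(colnames(fm), c("label", "subject"))
}

#' Per-channel column blocks of a feature matrix
#' @param fm A `feature_matrix`.
#' @return Named list mapping each channel label to its feature column names.
#' @export
channel_blocks <- function(fm) {
  fc <- feature_columns(fm)
  chan <- sub("\\.[^.]+$", "", fc)
  split(fc, factor(chan, levels = unique(chan)))
}

#' Write / read a feature matrix as CSV (+ JSON manifest)
#'
#' The CSV holds the feature columns plus `label` and `subject`; the optional
#' manifest records the measure and wavelet settings for provenance.
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path.
#' @param manifest Optional list (e.g. specs) written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path, manifest = NULL) {
  utils::write.csv(fm, path, row.names = FALSE)
  if (!is.null(manifest)) {
    jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(subject = "character"))
  df$label <- factor(df$label)
  class(df) <- c("feature_matrix", "data.frame")
  df
}
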