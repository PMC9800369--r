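# Greedy forward-addition (FA) channel selection over per-channel feature
# blocks. Iteration 1 scores each single channel; iteration m adds each
# remaining channel to the kept (m-1)-subset and keeps the best. For n
# channels this costs n(n+1)/2 classifier evaluations.

#' Forward-addition channel selection
#'
#' @param fm A `feature_matrix` whose feature columns group into per-channel
#'   blocks (as produced by [build_feature_matrix()]).
#' @param spec A [classifier_spec()].
#' @param evaluate Accuracy evaluator, `function(sub_fm) -> percent`. The
#'   default runs a single stratified k-fold CV ([kfold_cv()] with
#'   `repeats = 1`) with a fixed seed shared across all subset evaluations, so
#'   subsets are compared on identical folds.
#' @param n_channels Cap on the subset size (default: all channels).
#' @param k,seed Folds and seed of the default evaluator.
#' @return Object of class `selection_trace`: `max_acc[m]` = best accuracy
#'   with m channels, `selected[[m]]` = the m-channel subset (nested:
#'   `selected[[m]]` is `selected[[m-1]]` plus one channel),
#'   `n_evaluations` = total classifier evaluations.
#' @export
forward_addition <- function(fm, spec = classifier_spec(), evaluate = NULL,
                             n_channels = NULL, k = 10, seed = 1) {
  blocks <- channel_blocks(fm)
  sizes <- lengths(blocks)
  if (length(unique(sizes)) != 1) {
    stop("feature columns do not form equal per-channel blocks", call. = FALSE)
  }
  channels <- names(blocks)
  n <- length(channels)
  if (is.null(n_channels)) n_channels <- n
  if (n_channels < 1 || n_channels > n) {
    stop("n_channels must be in 1..", n, call. = FALSE)
  }
  n_eval <- 0L
  if (is.null(evaluate)) {
    evaluate <- function(sub_fm) {
      r <- kfold_cv(sub_fm, spec, k = k, repeats = 1, seed = seed)
      r$metrics$mean[r$metrics$metric == "accuracy"]
    }
  }
  score_subset <- function(chs) {
    cols <- unlist(blocks[chs], use.names = FALSE)
    sub <- fm[, c(cols, "label", "subject"), drop = FALSE]
    class(sub) <- c("feature_matrix", "data.frame")
    n_eval <<- n_eval + 1L
    evaluate(sub)
  }
  selected <- character(0)
  trace_sel <- vector("list", n_channels)
  max_acc <- numeric(n_channels)
  remaining <- channels
  for (m in seq_len(n_channels)) {
    accs <- vapply(remaining, function(ch) score_subset(c(selected, ch)), 0)
    best <- which.max(accs)   # ties: first (lowest channel index) wins
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
    max_acc[m] <- accs[best]
    trace_sel[[m]] <- selected
  }
  structure(list(max_acc = max_acc, selected = trace_sel,
                 n_evaluations = n_eval, channels = channels,
                 classifier = spec$kind),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %s, %d evaluations\n", x$classifier,
              x$n_evaluations))
  for (m in seq_along(x$max_acc)) {
    cat(sprintf("  m=%2d acc %6.2f%%  + %s\n", m, x$max_acc[m],
                utils::tail(x$selected[[m]], 1)))
  }
  invisible(x)
}
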