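# Classifiers (fixed literature parameters), confusion-matrix metrics,
# ROC/AUC, repeated stratified k-fold CV, and leave-one-subject-out CV.
#
# Positive class: PD (sensitivity = PD detection rate). Features are
# standardized with training-set statistics before KNN / SVM / LDA / LR
# (distance- and scale-sensitive methods); RF is scale-invariant but receives
# the same standardized input for uniformity.

#' Classifier settings
#'
#' Defaults follow the fixed parameter table: KNN with 3 neighbours and
#' euclidean distance; least-squares SVM with quadratic (or linear) kernel and
#' C = 0.2; random forest bagging 30 decision trees; LDA and logistic
#' regression with library defaults.
#'
#' @param kind One of `"KNN"`, `"SVM"`, `"RF"`, `"LDA"`, `"LR"`.
#' @param knn_k Number of neighbours (KNN). Default 3.
#' @param svm_kernel `"quadratic"` or `"linear"` (SVM). Default quadratic.
#' @param svm_C Regularization constant of the least-squares SVM. Default 0.2.
#' @param rf_n_learners Number of bagged trees (RF). Default 30.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("KNN", "SVM", "RF", "LDA", "LR"),
                            knn_k = 3, svm_kernel = c("quadratic", "linear"),
                            svm_C = 0.2, rf_n_learners = 30) {
  kind <- match.arg(kind)
  svm_kernel <- match.arg(svm_kernel)
  structure(list(kind = kind, knn_k = as.integer(knn_k),
                 knn_metric = "euclidean", svm_kernel = svm_kernel,
                 svm_method = "least_squares", svm_C = svm_C,
                 rf_n_learners = as.integer(rf_n_learners)),
            class = "classifier_spec")
}

# choose the positive class: PD groups over HC; otherwise the first level
.positive_class <- function(levels) {
  pd <- levels[grepl("^PD", levels)]
  if (length(pd) >= 1) pd[1] else levels[1]
}

# least-squares SVM: solve [[0, 1'], [1, K + I/C]] [b; a] = [0; y]
.lssvm_fit <- function(X, y01, kernel, C) {
  y <- ifelse(y01 == 1, 1, -1)
  K <- .lssvm_kernel(X, X, kernel)
  n <- nrow(X)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / C))
  sol <- tryCatch(solve(A, c(0, y)),
                  error = function(e) qr.solve(A, c(0, y), tol = 1e-12))
  list(b = sol[1], alpha = sol[-1], X = X, kernel = kernel)
}

.lssvm_kernel <- function(X, Y, kernel) {
  G <- X %*% t(Y)
  if (kernel == "linear") return(G)
  (G / ncol(X) + 1)^2   # quadratic, scaled by dimension for conditioning
}

.lssvm_decision <- function(fit, Xnew) {
  as.numeric(.lssvm_kernel(Xnew, fit$X, fit$kernel) %*% fit$alpha + fit$b)
}

#' Train on one split and predict another
#'
#' @param spec A [classifier_spec()].
#' @param train,test `feature_matrix` objects with identical feature layout;
#'   `train` must contain both classes.
#' @return List with `labels` (factor of predicted classes for `test`) and
#'   `scores` (continuous positive-class score per test row: posterior /
#'   decision value; for KNN the fraction of neighbours in the positive
#'   class), plus `positive` (the positive class name).
#' @export
fit_predict <- function(spec, train, test) {
  stopifnot(inherits(spec, "classifier_spec"))
  fc <- feature_columns(train)
  if (!identical(fc, feature_columns(test))) {
    stop("train/test feature layout mismatch", call. = FALSE)
  }
  ytr <- droplevels(factor(train$label))
  if (nlevels(ytr) < 2) stop("training set contains a single class",
                             call. = FALSE)
  if (nlevels(ytr) > 2) stop("binary classification only", call. = FALSE)
  pos <- .positive_class(levels(ytr))
  neg <- setdiff(levels(ytr), pos)
  Xtr <- as.matrix(train[, fc, drop = FALSE])
  Xte <- as.matrix(test[, fc, drop = FALSE])
  # standardize on training statistics; freeze degenerate columns
  mu <- colMeans(Xtr)
  sd_ <- apply(Xtr, 2, stats::sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  Xtr <- sweep(sweep(Xtr, 2, mu), 2, sd_, "/")
  Xte <- sweep(sweep(Xte, 2, mu), 2, sd_, "/")
  y01 <- as.integer(ytr == pos)

  scores <- switch(spec$kind,
    KNN = {
      pr <- class::knn(Xtr, Xte, ytr, k = spec$knn_k, prob = TRUE)
      winfrac <- attr(pr, "prob")
      ifelse(pr == pos, winfrac, 1 - winfrac)
    },
    SVM = {
      fit <- .lssvm_fit(Xtr, y01, spec$svm_kernel, spec$svm_C)
      .lssvm_decision(fit, Xte)
    },
    RF = {
      fit <- randomForest::randomForest(Xtr, ytr, ntree = spec$rf_n_learners)
      stats::predict(fit, Xte, type = "prob")[, pos]
    },
    LDA = {
      keep <- apply(Xtr, 2, stats::sd) > 0
      fit <- MASS::lda(Xtr[, keep, drop = FALSE], grouping = ytr)
      stats::predict(fit, Xte[, keep, drop = FALSE])$posterior[, pos]
    },
    LR = {
      df_tr <- data.frame(Xtr)
      df_te <- data.frame(Xte)
      colnames(df_te) <- colnames(df_tr)
      fit <- suppressWarnings(
        stats::glm(y ~ ., data = cbind(y = y01, df_tr),
                   family = stats::binomial()))
      suppressWarnings(
        as.numeric(stats::predict(fit, df_te, type = "response")))
    })
  labels <- factor(ifelse(scores > .score_cut(spec$kind), pos, neg),
                   levels = levels(ytr))
  # KNN hard labels come from the vote directly
  if (spec$kind == "KNN") {
    labels <- factor(
      as.character(class::knn(Xtr, Xte, ytr, k = spec$knn_k)),
      levels = levels(ytr))
  }
  list(labels = labels, scores = as.numeric(scores), positive = pos)
}

.score_cut <- function(kind) {
  switch(kind, SVM = 0, KNN = 0.5, 0.5)
}

#' Confusion counts from true/predicted labels
#'
#' @param truth,pred Factors over the same two classes.
#' @param positive The positive class name.
#' @return Object of class `confusion_counts` (TP, TN, FP, FN).
#' @export
confusion_counts <- function(truth, pred, positive) {
  truth <- as.character(truth); pred <- as.character(pred)
  structure(list(TP = sum(truth == positive & pred == positive),
                 TN = sum(truth != positive & pred != positive),
                 FP = sum(truth != positive & pred == positive),
                 FN = sum(truth == positive & pred != positive)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts (in percent)
#'
#' Accuracy, sensitivity (PD detection rate), specificity, precision, and
#' F-score. A metric whose denominator is zero is returned as `NA` (flagged
#' undefined), never silently 0.
#'
#' @param c A `confusion_counts` object or a list with TP/TN/FP/FN.
#' @return Named numeric vector (percent scale).
#' @export
compute_metrics <- function(c) {
  total <- c$TP + c$TN + c$FP + c$FN
  if (total == 0) stop("no evaluated rows", call. = FALSE)
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  acc <- 100 * (c$TP + c$TN) / total
  sens <- rate(c$TP, c$TP + c$FN)
  spec <- rate(c$TN, c$TN + c$FP)
  prec <- rate(c$TP, c$TP + c$FP)
  f <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  c(accuracy = acc, sensitivity = sens, specificity = spec,
    precision = prec, f_score = f)
}

#' ROC curve and AUC
#'
#' AUC by the trapezoid rule with rank-averaged ties (equals the Mann-Whitney
#' statistic P(score+ > score-) + 0.5 P(tie)).
#'
#' @param scores Continuous positive-class scores.
#' @param labels True labels.
#' @param positive Positive class name; default picks the PD group.
#' @return List with `roc_points` (data frame FPR/TPR) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  if (is.null(positive)) positive <- .positive_class(levels(labels))
  resp <- as.integer(labels == positive)
  r <- pROC::roc(response = resp, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  pts <- data.frame(FPR = rev(1 - r$specificities), TPR = rev(r$sensitivities))
  list(roc_points = pts, auc = as.numeric(pROC::auc(r)))
}

# shared fold-evaluation core
.run_folds <- function(fm, spec, folds, scheme, seed = NA) {
  fold_metrics <- list()
  pooled <- list(TP = 0, TN = 0, FP = 0, FN = 0)
  all_scores <- numeric(0)
  all_truth <- character(0)
  pos <- .positive_class(levels(factor(fm$label)))
  for (f in seq_along(folds)) {
    te_idx <- folds[[f]]
    train <- fm[-te_idx, , drop = FALSE]
    test <- fm[te_idx, , drop = FALSE]
    pr <- fit_predict(spec, train, test)
    cc <- confusion_counts(test$label, pr$labels, pr$positive)
    pooled <- Map(`+`, pooled, cc[c("TP", "TN", "FP", "FN")])
    fold_metrics[[f]] <- compute_metrics(cc)
    all_scores <- c(all_scores, pr$scores)
    all_truth <- c(all_truth, as.character(test$label))
  }
  fm_mat <- do.call(rbind, fold_metrics)
  roc <- if (length(unique(all_truth)) == 2) {
    roc_auc(all_scores, all_truth, positive = pos)
  } else list(roc_points = NULL, auc = NA_real_)
  metrics <- data.frame(
    metric = colnames(fm_mat),
    mean = colMeans(fm_mat, na.rm = TRUE),
    sd = apply(fm_mat, 2, stats::sd, na.rm = TRUE),
    row.names = NULL)
  metrics <- rbind(metrics,
                   data.frame(metric = "auc", mean = 100 * roc$auc, sd = NA))
  structure(list(metrics = metrics, fold_scores = fm_mat,
                 confusion = structure(pooled, class = "confusion_counts"),
                 roc_points = roc$roc_points, auc = roc$auc, scheme = scheme,
                 n_folds = length(folds), folds = folds, seed = seed,
                 classifier = spec$kind, positive = pos),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, %s, %d folds%s\n", x$classifier, x$scheme,
              x$n_folds, if (!is.na(x$seed)) paste0(", seed ", x$seed) else ""))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s %6.2f%s\n", m$metric[i], m$mean[i],
                if (is.na(m$sd[i])) "" else sprintf(" +/- %.2f", m$sd[i])))
  }
  invisible(x)
}

# stratified fold assignment: shuffle within class, deal round-robin
.stratified_folds <- function(labels, k) {
  fold_of <- integer(length(labels))
  for (cl in levels(factor(labels))) {
    idx <- sample(which(labels == cl))
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) which(fold_of == f))
}

#' Repeated stratified k-fold cross-validation
#'
#' @param fm A `feature_matrix`.
#' @param spec A [classifier_spec()].
#' @param k Folds per round (default 10, i.e. 90/10 train/test).
#' @param repeats Rounds with fresh seeded shuffles (default 10).
#' @param seed RNG seed for the fold shuffles.
#' @return An `eval_report`: per-metric mean and sd (percent) over all
#'   `k * repeats` fold scores, pooled confusion counts, ROC points, AUC.
#' @export
kfold_cv <- function(fm, spec = classifier_spec(), k = 10, repeats = 10,
                     seed = 1) {
  labels <- droplevels(factor(fm$label))
  tab <- table(labels)
  if (length(tab) < 2) {
    stop("need both classes present", call. = FALSE)
  }
  if (min(tab) < k) {
    stop("need at least k = ", k, " rows per class", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  folds <- list()
  for (r in seq_len(repeats)) folds <- c(folds, .stratified_folds(labels, k))
  rep <- .run_folds(fm, spec, folds, "kfold_repeated", seed)
  rep$k <- k
  rep$repeats <- repeats
  rep
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per distinct subject; all the subject's rows are held out
#' together, so train and test never share a subject.
#'
#' @param fm A `feature_matrix` with a `subject` column.
#' @param spec A [classifier_spec()].
#' @return An `eval_report` with one fold per subject.
#' @export
loso_cv <- function(fm, spec = classifier_spec()) {
  subs <- unique(fm$subject)
  per_class <- table(unique(fm[, c("subject", "label")])$label)
  if (any(per_class < 2)) {
    stop("need at least 2 subjects per class for LOSO", call. = FALSE)
  }
  if (anyDuplicated(unique(fm[, c("subject", "label")])$subject)) {
    stop("data error: a subject appears in both classes", call. = FALSE)
  }
  folds <- lapply(subs, function(s) which(fm$subject == s))
  names(folds) <- subs
  .run_folds(fm, spec, folds, "loso")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}
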