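# Classifiers, confusion metrics, ROC/AUC, and the two CV schemes.

test_that("confusion metrics match hand-computed ratios", {
  m <- compute_metrics(list(TP = 299, TN = 306, FP = 0, FN = 1))
  expect_equal(unname(m["accuracy"]), 100 * 605 / 606, tolerance = 1e-10)
  expect_equal(unname(m["sensitivity"]), 100 * 299 / 300, tolerance = 1e-10)
  expect_equal(unname(m["specificity"]), 100)
  expect_equal(unname(m["precision"]), 100)

  all_right <- compute_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_true(all(all_right == 100))

  degen <- compute_metrics(list(TP = 0, TN = 10, FP = 0, FN = 10))
  expect_equal(unname(degen["sensitivity"]), 0)
  expect_true(is.na(degen["precision"]))   # undefined, not silently 0
  expect_true(is.na(degen["f_score"]))
  expect_error(compute_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)), "rows")
})

test_that("accuracy is swap-invariant and sensitivity mirrors specificity", {
  set.seed(41)
  for (i in 1:20) {
    c1 <- as.list(setNames(sample(0:30, 4, TRUE), c("TP", "TN", "FP", "FN")))
    if (sum(unlist(c1)) == 0) next
    swap <- list(TP = c1$TN, TN = c1$TP, FP = c1$FN, FN = c1$FP)
    m1 <- compute_metrics(c1)
    m2 <- compute_metrics(swap)
    expect_equal(m1[["accuracy"]], m2[["accuracy"]])
    expect_equal(m1[["sensitivity"]], m2[["specificity"]])
  }
})

test_that("every classifier separates well-separated clusters perfectly", {
  fm <- make_cluster_fm(n_per_class = 60, gap = 10)
  te_idx <- c(1:15, 61 + (0:14))
  train <- fm[-te_idx, ]
  test <- fm[te_idx, ]
  for (kind in c("KNN", "SVM", "RF", "LDA", "LR")) {
    pr <- fit_predict(classifier_spec(kind), train, test)
    expect_equal(as.character(pr$labels), as.character(test$label),
                 info = kind)
    expect_length(pr$scores, nrow(test))
    expect_equal(pr$positive, "PD_off")
  }
})

test_that("KNN recovers the label of a triplicated training point", {
  train <- data.frame(f1 = c(1, 1, 1, 5, 6, 7), f2 = c(2, 2, 2, 9, 9, 9),
                      label = factor(c("PD_off", "PD_off", "PD_off",
                                       "HC", "HC", "HC")),
                      subject = paste0("s", 1:6))
  class(train) <- c("feature_matrix", "data.frame")
  test <- train[1, ]
  pr <- fit_predict(classifier_spec("KNN"), train, test)
  expect_equal(as.character(pr$labels), "PD_off")
})

test_that("degenerate training sets are rejected", {
  fm <- make_cluster_fm()
  one_class <- fm[fm$label == "HC", ]
  expect_error(fit_predict(classifier_spec("KNN"), one_class, fm[1:2, ]),
               "single class")
  mism <- fm
  colnames(mism)[1] <- "other"
  expect_error(fit_predict(classifier_spec("KNN"), fm, mism),
               "layout mismatch")
})

test_that("repeated k-fold produces k * repeats folds and is seed-deterministic", {
  fm <- make_cluster_fm(n_per_class = 30)
  r <- kfold_cv(fm, classifier_spec("KNN"), k = 10, repeats = 10, seed = 5)
  expect_equal(nrow(r$fold_scores), 100)
  expect_equal(r$n_folds, 100)
  expect_equal(r$metrics$mean[r$metrics$metric == "accuracy"], 100)
  expect_equal(r$metrics$sd[r$metrics$metric == "accuracy"], 0)
  r2 <- kfold_cv(fm, classifier_spec("KNN"), k = 10, repeats = 10, seed = 5)
  expect_identical(r$fold_scores, r2$fold_scores)
  expect_identical(r$confusion, r2$confusion)
  r3 <- kfold_cv(fm, classifier_spec("KNN"), k = 10, repeats = 10, seed = 6)
  expect_false(identical(r$folds, r3$folds))
  expect_error(kfold_cv(fm[1:12, ], classifier_spec("KNN"), k = 10),
               "both classes")
  expect_error(kfold_cv(fm[c(1:6, 31:36), ], classifier_spec("KNN"), k = 10),
               "per class")
})

test_that("label-independent features score near chance", {
  set.seed(44)
  n <- 600
  fm <- data.frame(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n),
                   label = factor(rep(c("HC", "PD_off"), each = n / 2)),
                   subject = paste0("s", seq_len(n)))
  class(fm) <- c("feature_matrix", "data.frame")
  r <- kfold_cv(fm, classifier_spec("KNN"), k = 10, repeats = 2, seed = 9)
  acc <- r$metrics$mean[r$metrics$metric == "accuracy"]
  expect_gt(acc, 45)
  expect_lt(acc, 55)
})

test_that("LOSO holds out whole subjects and never leaks them", {
  fm <- make_cluster_fm(n_per_class = 40, n_subjects = 4)
  r <- loso_cv(fm, classifier_spec("KNN"))
  expect_equal(r$n_folds, 8)   # 4 subjects per class
  expect_equal(r$scheme, "loso")
  expect_equal(r$metrics$mean[r$metrics$metric == "accuracy"], 100)
  # minimal viable case: two subjects per class, one fold per subject
  fm2 <- fm[fm$subject %in% c("HC_s1", "HC_s2", "PD_off_s1", "PD_off_s2"), ]
  expect_equal(loso_cv(fm2, classifier_spec("KNN"))$n_folds, 4)
  expect_error(loso_cv(fm[fm$subject %in% c("HC_s1", "PD_off_s1"), ],
                       classifier_spec("KNN")), "2 subjects per class")
  # a subject in both classes is a data error
  bad <- fm
  bad$subject[1] <- "PD_off_s1"
  expect_error(loso_cv(bad, classifier_spec("KNN")), "both classes")
  # leakage audit: no fold's held-out subjects appear in its training rows
  for (f in r$folds) {
    expect_length(intersect(fm$subject[f], fm$subject[-f]), 0)
  }
  expect_equal(sort(unname(unlist(r$folds))), seq_len(nrow(fm)))
})

test_that("AUC equals the brute-force pairwise statistic", {
  set.seed(46)
  for (i in 1:25) {
    n <- sample(10:50, 1)
    labels <- factor(c(rep("PD_off", 5), rep("HC", 5),
                       sample(c("PD_off", "HC"), n - 10, TRUE)))
    scores <- round(rnorm(n), sample(0:2, 1))   # ties included
    got <- roc_auc(scores, labels)$auc
    sp <- scores[labels == "PD_off"]
    sn <- scores[labels == "HC"]
    pairs <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(got, mean(pairs), tolerance = 1e-12)
  }
})

test_that("AUC is 1 for perfect ranking, 0 for reversed, ~0.5 for random", {
  labs <- factor(rep(c("PD_off", "HC"), each = 10))
  expect_equal(roc_auc(c(11:20, 1:10), labs)$auc, 1)
  expect_equal(roc_auc(c(1:10, 11:20), labs)$auc, 0)
  set.seed(47)
  labs2 <- factor(rep(c("PD_off", "HC"), each = 2500))
  r <- roc_auc(rnorm(5000), labs2)
  expect_equal(r$auc, 0.5, tolerance = 0.03)
  expect_true(all(diff(r$roc_points$TPR) >= 0))
  expect_true(all(diff(r$roc_points$FPR) >= 0))
  expect_error(roc_auc(rnorm(5), factor(rep("HC", 5))), "both classes")
})
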