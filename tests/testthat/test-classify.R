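test_that("positive labels follow the ICDSC-or-SOFA >= 3 rule", {
  expect_identical(label_positive(sofa = 0, icdsc = 0), FALSE)
  expect_identical(label_positive(sofa = 3, icdsc = 0), TRUE)
  expect_identical(label_positive(sofa = 2, icdsc = 3), TRUE)
  expect_identical(label_positive(sofa = c(0, 5), icdsc = c(4, 0)), c(TRUE, TRUE))
  expect_identical(label_positive(sofa = 2, icdsc = 2, threshold = 2), TRUE)
  expect_error(label_positive(NA, 1), "missing")
})

test_that("confusion metrics match hand-computed tables", {
  p <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(confusion_metrics(p, p)[c("accuracy", "sensitivity", "specificity")],
               list(accuracy = 100, sensitivity = 100, specificity = 100))
  expect_equal(confusion_metrics(!p, p)[c("accuracy", "sensitivity", "specificity")],
               list(accuracy = 0, sensitivity = 0, specificity = 0))
  # truth (P,P,N,N), predicted (P,N,N,N): 2x2 table by hand
  m <- confusion_metrics(c(TRUE, FALSE, FALSE, FALSE), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(m$accuracy, 75)
  expect_equal(m$sensitivity, 50)
  expect_equal(m$specificity, 100)
  expect_equal(unname(m$counts), c(1, 0, 2, 1))  # tp fp tn fn
  # one-class truth: undefined ratio reported as NA
  expect_true(is.na(confusion_metrics(c(TRUE, TRUE), c(TRUE, TRUE))$specificity))
  expect_error(confusion_metrics(TRUE, c(TRUE, FALSE)), "mismatch")
})

test_that("metrics weakly decrease as correct predictions flip to incorrect", {
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  pred <- truth
  prev <- confusion_metrics(pred, truth)
  for (i in seq_along(pred)) {
    pred[i] <- !pred[i]
    cur <- confusion_metrics(pred, truth)
    expect_lte(cur$accuracy, prev$accuracy)
    expect_lte(cur$sensitivity, prev$sensitivity)
    expect_lte(cur$specificity, prev$specificity)
    prev <- cur
  }
})

test_that("cross-validated SVM separates well-separated clouds perfectly", {
  set.seed(20)
  n <- 100
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  x <- matrix(rnorm(n * 2), n, 2) + ifelse(lab, 6, 0)  # 6-sd separation
  cv <- crossval_svm(x, lab, k = 5, seed = 1)
  expect_equal(cv$mean_accuracy, 100)
  expect_equal(cv$mean_sensitivity, 100)
  expect_equal(cv$mean_specificity, 100)
  expect_equal(cv$k, 5)
})

test_that("permuted labels give chance-level accuracy", {
  set.seed(21)
  accs <- replicate(20, {
    n <- 200
    x <- matrix(rnorm(n * 3), n, 3)
    lab <- sample(rep(c(TRUE, FALSE), each = n / 2))
    crossval_svm(x, lab, k = 5, seed = 1)$mean_accuracy
  })
  expect_lt(abs(mean(accs) - 50), 10)
})

test_that("fold assignment is keyed on sorted patient-days, not row order", {
  set.seed(22)
  n <- 40
  key <- data.frame(patient_id = sprintf("P%02d", rep(1:20, each = 2)),
                    day = rep(c(1, 3), 20))
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  x <- matrix(rnorm(n * 2), n, 2) + ifelse(lab, 1.5, 0)
  cv1 <- crossval_svm(x, lab, row_key = key, k = 5, seed = 9)
  perm <- sample(n)
  cv2 <- crossval_svm(x[perm, ], lab[perm], row_key = key[perm, ], k = 5, seed = 9)
  expect_equal(cv1$per_fold, cv2$per_fold)
  expect_equal(cv1$mean_accuracy, cv2$mean_accuracy)
})

test_that("ROC endpoints, ordering and degenerate cases behave", {
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  perfect <- roc_curve(c(3, 2.5, 2, 1, 0.5), lab)
  expect_equal(perfect$auc, 1)
  reversed <- roc_curve(c(0.5, 1, 2, 2.5, 3), lab)
  expect_equal(reversed$auc, 0)
  pts <- perfect$points
  expect_equal(pts[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1), ignore_attr = TRUE)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC equals the normalized Mann-Whitney U and matches pROC", {
  set.seed(23)
  for (i in 1:20) {
    n1 <- sample(5:30, 1); n0 <- sample(5:30, 1)
    scores <- c(rnorm(n1, 1), rnorm(n0))
    lab <- rep(c(TRUE, FALSE), c(n1, n0))
    auc <- roc_curve(scores, lab)$auc
    u <- suppressWarnings(stats::wilcox.test(scores[lab], scores[!lab])$statistic)
    expect_equal(auc, unname(u) / (n1 * n0), tolerance = 1e-9)
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- as.numeric(pROC::auc(pROC::roc(as.numeric(lab), scores, quiet = TRUE,
                                            direction = "<")))
      expect_equal(auc, ref, tolerance = 1e-9)
    }
  }
  # random-score null centers at 1/2
  set.seed(24)
  aucs <- replicate(20, roc_curve(rnorm(1000), rep(c(TRUE, FALSE), 500))$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("patient-split classifier issues correct/wrong/undecided verdicts", {
  # 10 patients x 4 measurements in 1-D component space, perfectly separable
  set.seed(25)
  key <- data.frame(patient_id = sprintf("P%02d", rep(1:10, each = 4)),
                    day = rep(1, 40))
  lab <- rep(rep(c(TRUE, FALSE), 5), each = 4)
  comp <- matrix(ifelse(lab, 2, -2) + rnorm(40, 0, 0.1), ncol = 1)
  res <- patient_split_classifier(comp, key, lab, n_train = 5, seed = 1)
  expect_equal(res$verdicts$verdict, rep("correct", 5))
  expect_equal(res$kmeans_agreement, 1)

  # push one test patient's measurements across the boundary -> mixed
  comp2 <- comp
  rows <- which(key$patient_id == "P07")[1:2]
  comp2[rows] <- -comp2[rows]
  res2 <- patient_split_classifier(comp2, key, lab, n_train = 5, seed = 1)
  expect_equal(res2$verdicts$verdict[res2$verdicts$patient_id == "P07"], "undecided")
  # flip all of a patient's measurements -> wrong
  comp3 <- comp
  comp3[key$patient_id == "P08"] <- 2
  res3 <- patient_split_classifier(comp3, key, lab, n_train = 5, seed = 1)
  expect_equal(res3$verdicts$verdict[res3$verdicts$patient_id == "P08"], "wrong")
  expect_error(patient_split_classifier(comp, key, lab, n_train = 9), "2 patients")
})
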