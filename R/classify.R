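#' Binary labelling of patient-days
#'
#' A patient-day is labelled positive when its ICDSC or SOFA score
#' reaches the threshold (default 3): the organ-failure/delirium
#' composite endpoint of the screening classifier.
#'
#' @param sofa,icdsc Integer score vectors (no missing values).
#' @param threshold Score cut-off, default 3.
#' @return Logical vector (`TRUE` = positive).
#' @export
#' @examples
#' label_positive(sofa = c(0, 3, 2), icdsc = c(0, 0, 3))
label_positive <- function(sofa, icdsc, threshold = 3) {
  if (anyNA(sofa) || anyNA(icdsc)) stopf("missing SOFA/ICDSC score")
  sofa >= threshold | icdsc >= threshold
}

#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity (true-positive rate) and specificity
#' (true-negative rate) in percent, plus the raw confusion counts.
#' Ratios with a zero denominator (a class absent from `truth`) are
#' reported as `NA` and are excluded from cross-validation averages.
#'
#' @param predicted,truth Logical vectors of equal length.
#' @return List with `accuracy`, `sensitivity`, `specificity` (percent)
#'   and `counts` (tp, fp, tn, fn).
#' @export
confusion_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stopf("length mismatch")
  predicted <- as.logical(predicted); truth <- as.logical(truth)
  tp <- sum(predicted & truth); tn <- sum(!predicted & !truth)
  fp <- sum(predicted & !truth); fn <- sum(!predicted & truth)
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(accuracy = rate(tp + tn, length(truth)),
       sensitivity = rate(tp, tp + fn),
       specificity = rate(tn, tn + fp),
       counts = c(tp = tp, fp = fp, tn = tn, fn = fn))
}

# deterministic stratified fold assignment; optionally grouped so that
# all rows of a group (patient) share a fold, stratified by the group's
# majority label
make_folds <- function(labels, k, group = NULL) {
  n <- length(labels)
  fold <- integer(n)
  if (is.null(group)) {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    ug <- unique(group)
    glab <- vapply(ug, function(g) mean(labels[group == g]) >= 0.5, logical(1))
    gfold <- integer(length(ug))
    for (cls in c(TRUE, FALSE)) {
      idx <- which(glab == cls)
      if (length(idx)) gfold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold <- gfold[match(group, ug)]
  }
  fold
}

#' Cross-validated SVM classification
#'
#' Stratified k-fold cross-validation (default fivefold) of a
#' support-vector machine on the supplied feature columns. Rows are
#' keyed and sorted by `(patient_id, day)` before fold assignment so the
#' folds do not depend on input row order. With
#' `group_by_patient = TRUE` (default) all rows of a patient share a
#' fold, avoiding leakage between a patient's days.
#'
#' @param x Numeric matrix/data.frame of features (rows = patient-days).
#' @param labels Logical vector of positive labels.
#' @param row_key `data.frame` with `patient_id` and `day` columns
#'   aligned with `x` (used for sorting and grouping); optional.
#' @param k Number of folds.
#' @param seed Integer seed for the fold assignment.
#' @param group_by_patient Assign folds at patient level.
#' @param kernel SVM kernel, `"linear"` (default) or `"radial"`.
#' @param cost SVM cost parameter.
#' @param balanced Weight classes inversely to their training frequency
#'   (default). Positive labels dominate screening cohorts; without
#'   weighting the maximum-margin fit can collapse onto the majority
#'   class and report no specificity at all.
#' @return Object of class `acg_cv_metrics`: `per_fold` data.frame,
#'   `mean_accuracy`, `mean_sensitivity`, `mean_specificity` (percent,
#'   averaged over folds with defined values), `k`, `seed`, plus pooled
#'   out-of-fold `scores` (decision values), `labels` and `row_key` for
#'   ROC analysis.
#' @export
crossval_svm <- function(x, labels, row_key = NULL, k = 5, seed = 1L,
                         group_by_patient = TRUE, kernel = c("linear", "radial"),
                         cost = 1, balanced = TRUE) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  labels <- as.logical(labels)
  if (nrow(x) < k) stopf("need at least k rows")
  if (length(unique(labels)) < 2) stopf("both classes must be present")

  if (!is.null(row_key)) {
    ord <- order(row_key$patient_id, row_key$day)
    x <- x[ord, , drop = FALSE]; labels <- labels[ord]
    row_key <- row_key[ord, , drop = FALSE]
    group <- if (group_by_patient) row_key$patient_id else NULL
  } else {
    group <- NULL
  }

  set.seed(as.integer(seed))
  fold <- make_folds(labels, k, group)

  per_fold <- list()
  scores <- rep(NA_real_, length(labels))
  preds <- rep(NA, length(labels))
  for (f in seq_len(k)) {
    test <- which(fold == f); train <- which(fold != f)
    if (length(test) == 0 || length(unique(labels[train])) < 2) {
      per_fold[[f]] <- data.frame(fold = f, accuracy = NA_real_,
                                  sensitivity = NA_real_, specificity = NA_real_,
                                  tp = NA, fp = NA, tn = NA, fn = NA)
      next
    }
    ytr <- factor(labels[train], levels = c(FALSE, TRUE))
    cw <- if (balanced) {
      w <- length(ytr) / (2 * table(ytr)); stats::setNames(as.numeric(w), names(w))
    } else NULL
    fit <- e1071::svm(x = x[train, , drop = FALSE], y = ytr,
                      kernel = kernel, cost = cost, scale = FALSE,
                      class.weights = cw)
    pr <- stats::predict(fit, x[test, , drop = FALSE], decision.values = TRUE)
    dv <- as.numeric(attr(pr, "decision.values"))
    # orient decision values so larger means more positive
    if (colnames(attr(pr, "decision.values"))[1] == "FALSE/TRUE") dv <- -dv
    pred <- pr == "TRUE"
    preds[test] <- pred
    scores[test] <- dv
    cm <- confusion_metrics(pred, labels[test])
    per_fold[[f]] <- data.frame(fold = f, accuracy = cm$accuracy,
                                sensitivity = cm$sensitivity,
                                specificity = cm$specificity,
                                tp = cm$counts["tp"], fp = cm$counts["fp"],
                                tn = cm$counts["tn"], fn = cm$counts["fn"])
  }
  per_fold <- do.call(rbind, per_fold)
  rownames(per_fold) <- NULL
  if (anyNA(per_fold$sensitivity) || anyNA(per_fold$specificity)) {
    message("some folds had a class absent; undefined fold metrics excluded from means")
  }
  structure(list(per_fold = per_fold,
                 mean_accuracy = mean(per_fold$accuracy, na.rm = TRUE),
                 mean_sensitivity = mean(per_fold$sensitivity, na.rm = TRUE),
                 mean_specificity = mean(per_fold$specificity, na.rm = TRUE),
                 k = k, seed = as.integer(seed),
                 scores = scores, labels = labels, predictions = preds,
                 row_key = row_key),
            class = "acg_cv_metrics")
}

#' @export
print.acg_cv_metrics <- function(x, ...) {
  cat(sprintf("ACG %d-fold CV: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
              x$k, x$mean_accuracy, x$mean_sensitivity, x$mean_specificity))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Receiver operating characteristic of continuous scores against
#' binary labels: thresholds are swept over the distinct score values
#' (larger score = more positive) and the area under the curve is
#' computed by the trapezoid rule, which equals the Mann-Whitney U
#' statistic normalised by `n_pos * n_neg`.
#'
#' @param scores Numeric decision values.
#' @param labels Logical vector (`TRUE` = positive).
#' @return Object of class `acg_roc`: `points` data.frame (fpr, tpr,
#'   from (0,0) to (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stopf("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & !labels), numeric(1))
  tpr <- c(0, tp / n_pos, 1)
  fpr <- c(0, fp / n_neg, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "acg_roc")
}

#' @export
print.acg_roc <- function(x, ...) {
  cat(sprintf("ACG ROC curve: %d points, AUC %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Per-patient classifier on a first-half/last-half patient split
#'
#' Trains on the measurement-level GA-component scores of the first
#' `n_train` patients (enrollment order) and predicts every single
#' measurement of the remaining patients. K-means clustering (k = 2) of
#' the training component space provides an unsupervised view of the
#' class structure (reported as cluster/label agreement); the
#' predictions come from an SVM. A test patient is `correct` when all
#' of its measurement-level predictions match its patient-day labels,
#' `wrong` when none do, and `undecided` when they disagree.
#'
#' @param components Numeric matrix of measurement-level GA-component
#'   scores (one row per single measurement).
#' @param row_key `data.frame` with `patient_id`, `day` aligned to
#'   `components`.
#' @param labels Logical labels aligned to `components` (patient-day
#'   label replicated over the day's measurements).
#' @param n_train Number of training patients (default half).
#' @param seed Integer seed (k-means restarts, SVM is deterministic).
#' @param kernel,cost SVM settings, see [crossval_svm()].
#' @return List with `verdicts` (`data.frame`: patient_id, verdict,
#'   n_measurements, n_correct), `kmeans_agreement` (fraction of
#'   training measurements whose cluster matches the majority-label
#'   alignment), and the fitted split.
#' @export
patient_split_classifier <- function(components, row_key, labels,
                                     n_train = NULL, seed = 1L,
                                     kernel = "linear", cost = 1) {
  components <- as.matrix(components)
  labels <- as.logical(labels)
  patients <- sort(unique(row_key$patient_id))
  if (is.null(n_train)) n_train <- length(patients) %/% 2
  if (n_train < 2 || length(patients) - n_train < 2) {
    stopf("need at least 2 patients on each side of the split")
  }
  train_pat <- patients[seq_len(n_train)]
  train <- row_key$patient_id %in% train_pat
  if (length(unique(labels[train])) < 2) stopf("training split has one class only")

  set.seed(as.integer(seed))
  km <- NULL
  for (attempt in seq_len(10)) {
    km <- tryCatch(stats::kmeans(components[train, , drop = FALSE], centers = 2,
                                 nstart = 5),
                   error = function(e) NULL)
    if (!is.null(km) && all(km$size > 0)) break
    km <- NULL
  }
  if (is.null(km)) stopf("degenerate k-means clustering after 10 restarts")
  # align cluster ids to the majority label of each cluster
  cl_pos <- which.max(tapply(labels[train], km$cluster, mean))
  km_agree <- mean((km$cluster == cl_pos) == labels[train])

  fit <- e1071::svm(x = components[train, , drop = FALSE],
                    y = factor(labels[train], levels = c(FALSE, TRUE)),
                    kernel = kernel, cost = cost, scale = FALSE)
  test <- !train
  pred <- stats::predict(fit, components[test, , drop = FALSE]) == "TRUE"
  test_key <- row_key[test, , drop = FALSE]
  test_lab <- labels[test]

  verdicts <- do.call(rbind, lapply(setdiff(patients, train_pat), function(p) {
    sel <- test_key$patient_id == p
    hits <- pred[sel] == test_lab[sel]
    verdict <- if (all(hits)) "correct" else if (!any(hits)) "wrong" else "undecided"
    data.frame(patient_id = p, verdict = verdict,
               n_measurements = sum(sel), n_correct = sum(hits),
               stringsAsFactors = FALSE)
  }))
  list(verdicts = verdicts, kmeans_agreement = km_agree,
       train_patients = train_pat, seed = as.integer(seed))
}
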