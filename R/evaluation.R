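#' Confusion matrix at a decision threshold
#'
#' A fragment is predicted positive iff its score is at or above the
#' threshold.
#'
#' @param labels 0/1 vector (1 = positive).
#' @param scores probability vector of the same length.
#' @param threshold decision threshold in [0, 1], default 0.5.
#' @return Object of class `"confusion"`: list with integer `TP`, `FP`,
#'   `TN`, `FN` and the `threshold`.
#' @export
confusion <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  pred <- scores >= threshold
  pos <- labels == 1
  structure(list(TP = sum(pred & pos), FP = sum(pred & !pos),
                 TN = sum(!pred & !pos), FN = sum(!pred & pos),
                 threshold = threshold),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2, byrow = TRUE,
              dimnames = list(c("actual +", "actual -"),
                              c("pred +", "pred -")))
  cat("Confusion matrix (threshold ", x$threshold, ")\n", sep = "")
  print(m)
  invisible(x)
}

#' Accuracy, precision, recall and F-score from a confusion matrix
#'
#' Accuracy = (TP+TN)/total; precision = TP/(TP+FP); recall = TP/(TP+FN);
#' F = 2 x precision x recall / (precision + recall). Precision is
#' undefined (NA, with a warning) when no positives are predicted, recall
#' when no positives exist; the F-score requires both.
#'
#' @param cm a [confusion()] object (or list with TP/FP/TN/FN).
#' @return Object of class `"ubi_metrics"`: list with `accuracy`,
#'   `precision`, `recall`, `f_score`, `auc` (NA here; see [roc_auc()]).
#' @export
metrics_from_confusion <- function(cm) {
  total <- cm$TP + cm$FP + cm$TN + cm$FN
  if (total == 0) stop("empty confusion matrix")
  precision <- if (cm$TP + cm$FP == 0) {
    warning("precision undefined: no predicted positives"); NA_real_
  } else cm$TP / (cm$TP + cm$FP)
  recall <- if (cm$TP + cm$FN == 0) {
    warning("recall undefined: no actual positives"); NA_real_
  } else cm$TP / (cm$TP + cm$FN)
  f <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  structure(list(accuracy = (cm$TP + cm$TN) / total, precision = precision,
                 recall = recall, f_score = f, auc = NA_real_),
            class = "ubi_metrics")
}

#' @export
print.ubi_metrics <- function(x, ...) {
  v <- unlist(x)
  cat(paste(sprintf("%s = %s", names(v),
                    ifelse(is.na(v), "NA", sprintf("%.4f", v))),
            collapse = ", "), "\n")
  invisible(x)
}

#' Area under the ROC curve (rank formulation)
#'
#' Mann-Whitney statistic: the probability that a random positive
#' outscores a random negative, ties counted 1/2. Computed from midranks,
#' so it handles tied scores exactly.
#'
#' @param labels 0/1 vector containing both classes.
#' @param scores numeric score vector.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  n1 <- as.numeric(sum(labels == 1)); n0 <- as.numeric(sum(labels == 0))
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve and its trapezoidal area
#'
#' Sweeps the decision threshold over the distinct scores and returns the
#' (FPR, TPR) points plus the trapezoidal integral. On the same data the
#' trapezoidal area equals the rank-based [roc_auc()].
#'
#' @inheritParams roc_auc
#' @return List with `points` (data frame `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(labels, scores) {
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0) {
    stop("both classes must be present")
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab == 1); fp <- cumsum(lab == 0)
  last <- !duplicated(sc, fromLast = TRUE)  # one point per distinct score
  tpr <- c(0, tp[last] / sum(labels == 1))
  fpr <- c(0, fp[last] / sum(labels == 0))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Threshold metrics plus AUC for scored fragments
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold for the confusion-based metrics.
#' @return An `"ubi_metrics"` with the `auc` slot filled.
#' @export
evaluate_scores <- function(labels, scores, threshold = 0.5) {
  m <- metrics_from_confusion(confusion(labels, scores, threshold))
  m$auc <- roc_auc(labels, scores)
  m
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repeat, partitions the dataset into k near-equal folds
#' (stratified by label, so the class balance is preserved in every
#' fold); each fold is held out once while the trainer fits on the rest.
#' The summary aggregates all k x repeats metric sets.
#'
#' @param dataset labeled fragment data frame.
#' @param k number of folds (>= 2).
#' @param repeats number of repeated partitions.
#' @param trainer function `(train_set, test_set, seed)` returning a
#'   named list / vector of metrics (e.g. from [evaluate_scores()]).
#' @param seeds integer vector of length `repeats`, one seed per repeat.
#' @param stratified stratify folds by label (default TRUE).
#' @return Object of class `"cv_summary"`: list with `runs` (data frame,
#'   one row per fold x repeat), `mean`, `sd`, `k`, `repeats`, `seeds`.
#' @export
repeated_kfold <- function(dataset, k = 10L, repeats = 5L, trainer,
                           seeds = seq_len(repeats), stratified = TRUE) {
  if (k < 2) stop("k must be >= 2")
  if (length(seeds) != repeats) stop("need one seed per repeat")
  labs <- dataset$label
  if (stratified && min(table(labs)) < k) {
    stop("k exceeds the size of the smallest class")
  }
  runs <- list()
  for (r in seq_len(repeats)) {
    set.seed(seeds[r])
    fold <- integer(nrow(dataset))
    if (stratified) {
      for (cl in unique(labs)) {
        idx <- which(labs == cl)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      fold <- sample(rep_len(seq_len(k), nrow(dataset)))
    }
    for (f in seq_len(k)) {
      test <- dataset[fold == f, , drop = FALSE]
      train <- dataset[fold != f, , drop = FALSE]
      m <- trainer(train, test, seeds[r] * 1000L + f)
      runs[[length(runs) + 1L]] <-
        data.frame(repeat_ = r, fold = f,
                   as.data.frame(m[c("accuracy", "precision", "recall",
                                     "f_score", "auc")]))
    }
  }
  runs <- do.call(rbind, runs)
  metric_cols <- c("accuracy", "precision", "recall", "f_score", "auc")
  structure(list(runs = runs,
                 mean = colMeans(runs[metric_cols], na.rm = TRUE),
                 sd = vapply(runs[metric_cols], sd, numeric(1), na.rm = TRUE),
                 k = k, repeats = repeats, seeds = seeds),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %d repeat(s): %d runs\n",
              x$k, x$repeats, nrow(x$runs)))
  for (m in names(x$mean)) {
    cat(sprintf("  %-9s %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}

#' Cross-validation trainer for the CNN classifier
#'
#' Builds a closure suitable for [repeated_kfold()]: each call constructs
#' an embedding-initialized network, fine-tunes it on the training fold
#' and evaluates on the held-out fold.
#'
#' @param embedding an `"embedding_matrix"` (pretrained or random).
#' @param vocab the matching vocabulary.
#' @param window fragment window length.
#' @param cnn a [cnn_config()].
#' @param train a [train_config()]; its `seed` is replaced per fold.
#' @param threshold decision threshold for the fold metrics.
#' @return A function `(train_set, test_set, seed)` returning an
#'   `"ubi_metrics"` list.
#' @export
cnn_trainer <- function(embedding, vocab, window = 31L, cnn = cnn_config(),
                        train = train_config(), threshold = 0.5) {
  force(embedding); force(vocab); force(window); force(cnn); force(train)
  function(train_set, test_set, seed) {
    cfg <- train
    cfg$seed <- as.integer(seed %% .Machine$integer.max)
    model <- ubi_cnn(train_set, embedding, vocab, window = window,
                     cnn = cnn, train = cfg)
    scores <- predict_fragments(model, test_set)
    evaluate_scores(as.numeric(test_set$label == "positive"), scores,
                    threshold)
  }
}
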