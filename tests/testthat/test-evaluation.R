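test_that("confusion counts follow the >= threshold rule", {
  cm <- confusion(c(1, 0), c(0.9, 0.1))
  expect_equal(unlist(cm[c("TP", "FP", "TN", "FN")]),
               c(TP = 1, FP = 0, TN = 1, FN = 0))
  # ties at the threshold count as predicted positive
  cm2 <- confusion(c(1, 0), c(0.5, 0.5), threshold = 0.5)
  expect_equal(cm2$TP, 1)
  expect_equal(cm2$FP, 1)
  set.seed(1)
  cm3 <- confusion(rbinom(10, 1, 0.5), runif(10))
  expect_equal(cm3$TP + cm3$FP + cm3$TN + cm3$FN, 10)
  expect_error(confusion(c(1, 0), 0.5), "length")
})

test_that("metrics match the defining equations", {
  m <- metrics_from_confusion(list(TP = 1, FP = 0, TN = 1, FN = 0))
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f_score")]),
               c(accuracy = 1, precision = 1, recall = 1, f_score = 1))
  m2 <- metrics_from_confusion(list(TP = 3, FP = 1, TN = 4, FN = 2))
  expect_equal(m2$accuracy, 0.7)
  expect_equal(m2$precision, 0.75)
  expect_equal(m2$recall, 0.6)
  expect_equal(m2$f_score, 2 * 0.75 * 0.6 / 1.35)
  expect_warning(m3 <- metrics_from_confusion(list(TP = 0, FP = 0, TN = 5,
                                                   FN = 2)),
                 "precision undefined")
  expect_true(is.na(m3$precision))
  expect_true(is.na(m3$f_score))
  expect_error(metrics_from_confusion(list(TP = 0, FP = 0, TN = 0, FN = 0)),
               "empty")
})

test_that("metrics agree with brute-force recounts from raw scores", {
  set.seed(2)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    labels <- rbinom(n, 1, 0.5)
    scores <- round(runif(n), 2)  # rounding forces ties
    t <- runif(1)
    cm <- confusion(labels, scores, t)
    pred <- as.integer(scores >= t)
    expect_equal(cm$TP, sum(pred == 1 & labels == 1))
    expect_equal(cm$FP, sum(pred == 1 & labels == 0))
    expect_equal(cm$TN, sum(pred == 0 & labels == 0))
    expect_equal(cm$FN, sum(pred == 0 & labels == 1))
    if (cm$TP + cm$FP > 0 && cm$TP + cm$FN > 0) {
      m <- metrics_from_confusion(cm)
      expect_equal(m$accuracy, mean(pred == labels))
      expect_equal(m$precision, sum(pred & labels) / sum(pred))
      expect_equal(m$recall, sum(pred & labels) / sum(labels))
    }
  }
})

test_that("rank AUC matches pairwise enumeration, pROC and the trapezoid", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1)), 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)

  set.seed(3)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
    scores <- round(runif(n), 1)
    got <- roc_auc(labels, scores)
    # brute force over all positive-negative pairs, ties at 1/2
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    grid <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(got, mean(grid))
    expect_equal(got, roc_curve(labels, scores)$auc, tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(4)
  labels <- rbinom(200, 1, 0.5); scores <- round(runif(200), 2)
  expect_equal(roc_auc(labels, scores),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE, direction = "<"))))
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("repeated k-fold produces k x repeats stratified runs", {
  ds <- gen_labeled_fragments(60, 60, motif_spec(effect = 1), seed = 5)
  # cheap deterministic trainer: score = fraction of R in the fragment
  trainer <- function(train, test, seed) {
    sc <- vapply(strsplit(test$sequence, ""),
                 function(ch) mean(ch == "R"), numeric(1))
    evaluate_scores(as.numeric(test$label == "positive"), sc)
  }
  cv <- repeated_kfold(ds, k = 10, repeats = 5, trainer = trainer,
                       seeds = 1:5)
  expect_equal(nrow(cv$runs), 50)
  expect_equal(cv$mean[["accuracy"]], mean(cv$runs$accuracy))
  cv2 <- repeated_kfold(ds, k = 10, repeats = 5, trainer = trainer,
                        seeds = 1:5)
  expect_identical(cv$runs, cv2$runs)

  # a constant trainer has zero dispersion
  const_trainer <- function(train, test, seed) {
    list(accuracy = 0.7, precision = 0.7, recall = 0.7, f_score = 0.7,
         auc = 0.7)
  }
  cv3 <- repeated_kfold(ds, k = 4, repeats = 2, trainer = const_trainer,
                        seeds = 1:2)
  expect_equal(unname(cv3$sd["accuracy"]), 0)
  expect_error(repeated_kfold(ds, k = 100, repeats = 1, trainer = trainer,
                              seeds = 1), "smallest class")
})

test_that("folds are balanced, disjoint and exhaustive", {
  ds <- gen_labeled_fragments(55, 55, motif_spec(effect = 1), seed = 6)
  seen <- list()
  trainer <- function(train, test, seed) {
    seen[[length(seen) + 1]] <<- test
    # stratification: class balance preserved within 1 per fold
    expect_lte(abs(sum(test$label == "positive") -
                   sum(test$label == "negative")), 1)
    list(accuracy = 0.5, precision = 0.5, recall = 0.5, f_score = 0.5,
         auc = 0.5)
  }
  repeated_kfold(ds, k = 5, repeats = 1, trainer = trainer, seeds = 3)
  sizes <- vapply(seen, nrow, 1L)
  expect_lte(max(sizes) - min(sizes), 2)  # one per class
  all_ids <- unlist(lapply(seen, function(d) d$protein_id))
  expect_equal(sort(all_ids), sort(ds$protein_id))  # partition, no overlap
})

test_that("evaluate_scores combines threshold metrics with AUC", {
  set.seed(7)
  labels <- rbinom(100, 1, 0.5)
  scores <- ifelse(labels == 1, runif(100, 0.3, 1), runif(100, 0, 0.7))
  m <- evaluate_scores(labels, scores)
  expect_equal(m$auc, roc_auc(labels, scores))
  expect_equal(m$accuracy,
               metrics_from_confusion(confusion(labels, scores))$accuracy)
})
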