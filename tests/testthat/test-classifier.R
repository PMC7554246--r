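test_that("built model transfers the embedding and has the right shapes", {
  v <- build_vocab(2)
  emb <- random_embedding(v, 20, seed = 1)
  model <- build_ubi_cnn(emb, v, window = 31)
  # embedding layer equals the supplied matrix exactly before training
  expect_identical(model$params$E, unname(unclass(emb)[, ]))
  # valid padding: 30 -> 28 -> 14 -> 12 -> 6 -> 4 -> 2, flatten 2 x 128
  expect_equal(dim(model$params$dense_W[[1]]), c(256, 128))
  expect_equal(dim(model$params$conv_W[[1]]), c(3 * 20, 128))
  expect_equal(dim(model$params$conv_W[[2]]), c(3 * 128, 128))
  expect_equal(dim(model$params$dense_W[[3]]), c(64, 1))
  # biases start at zero, conv/dense weights Gaussian(0, 0.01)
  expect_true(all(model$params$conv_b[[1]] == 0))
  expect_lt(sd(model$params$dense_W[[1]]), 0.02)
  # parameter count matches the closed form
  expected <- 401 * 20 +
    (3 * 20 * 128 + 128) + 2 * (3 * 128 * 128 + 128) +
    (256 * 128 + 128) + (128 * 64 + 64) + (64 * 1 + 1)
  expect_equal(n_parameters(model), expected)
  expect_error(build_ubi_cnn(unclass(emb)[1:100, ], v), "rows")
})

test_that("forward scores are probabilities strictly inside (0, 1)", {
  v <- build_vocab(2)
  model <- build_ubi_cnn(random_embedding(v, 10, seed = 2), v,
                         cnn = tiny_cnn(), train = tiny_train())
  sc <- predict_fragments(model, random_fragments(25, seed = 3))
  expect_length(sc, 25)
  expect_true(all(sc > 0 & sc < 1))
})

test_that("binary cross-entropy matches its defining formula", {
  eps <- 1e-7
  expect_equal(bce_loss(c(1, 0), c(1 - eps, eps)), eps, tolerance = 1e-6)
  expect_equal(bce_loss(c(1, 0, 1, 1), rep(0.5, 4)), log(2), tolerance = 1e-9)
  expect_equal(bce_loss(1, 1e-12), -log(eps), tolerance = 1e-6)  # clipped
  expect_true(is.finite(bce_loss(c(1, 0), c(0, 1))))
  expect_error(bce_loss(c(1, 0), 0.5), "length")
})

test_that("training reduces the loss on a strongly separable set", {
  v <- build_vocab(2)
  ds <- gen_labeled_fragments(150, 150, motif_spec(effect = 15), seed = 4)
  emb <- random_embedding(v, 10, sigma = 0.1, seed = 5)
  fit <- ubi_cnn(ds, emb, v, cnn = tiny_cnn(), train = tiny_train(epochs = 25))
  expect_lt(fit$history[length(fit$history)], fit$history[1])
  expect_true(all(is.finite(fit$history)))
  sc <- predict_fragments(fit, ds)
  expect_gt(roc_auc(as.numeric(ds$label == "positive"), sc), 0.8)
})

test_that("training errors on degenerate datasets", {
  v <- build_vocab(2)
  model <- build_ubi_cnn(random_embedding(v, 10, seed = 1), v,
                         cnn = tiny_cnn(), train = tiny_train())
  expect_error(train_ubi_cnn(model, as_fragment_df(character())), "empty")
  expect_error(
    train_ubi_cnn(model, as_fragment_df(random_fragments(5), "positive")),
    "both classes")
})

test_that("freezing keeps the embedding bit-identical through training", {
  v <- build_vocab(2)
  ds <- gen_labeled_fragments(60, 60, motif_spec(effect = 10), seed = 6)
  emb <- random_embedding(v, 10, seed = 7)
  frozen <- ubi_cnn(ds, emb, v, cnn = tiny_cnn(),
                    train = tiny_train(epochs = 3, freeze_embedding = TRUE))
  expect_identical(frozen$params$E, unname(unclass(emb)[, ]))
  tuned <- ubi_cnn(ds, emb, v, cnn = tiny_cnn(),
                   train = tiny_train(epochs = 3))
  expect_false(identical(tuned$params$E, unname(unclass(emb)[, ])))
})

test_that("training is deterministic given the seed", {
  v <- build_vocab(2)
  ds <- gen_labeled_fragments(60, 60, motif_spec(effect = 5), seed = 8)
  emb <- random_embedding(v, 10, seed = 9)
  f1 <- ubi_cnn(ds, emb, v, cnn = tiny_cnn(), train = tiny_train(epochs = 4))
  f2 <- ubi_cnn(ds, emb, v, cnn = tiny_cnn(), train = tiny_train(epochs = 4))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("fragment scoring is order-, duplicate- and batch-invariant", {
  v <- build_vocab(2)
  ds <- gen_labeled_fragments(40, 40, motif_spec(effect = 5), seed = 10)
  emb <- random_embedding(v, 10, seed = 11)
  fit <- ubi_cnn(ds, emb, v, cnn = tiny_cnn(), train = tiny_train(epochs = 3))
  frs <- ds$sequence[1:20]
  sc <- predict_fragments(fit, frs)
  perm <- sample(20)
  expect_equal(predict_fragments(fit, frs[perm]), sc[perm])
  expect_equal(predict_fragments(fit, c(frs[1], frs[1]))[1],
               predict_fragments(fit, c(frs[1], frs[1]))[2])
  expect_equal(predict_fragments(fit, frs, batch_size = 1), sc)
  expect_equal(predict_fragments(fit, frs, batch_size = 7), sc)
  expect_error(predict_fragments(fit, "KKK"), "length mismatch")
})

test_that("whole-protein prediction scores every lysine", {
  v <- build_vocab(2)
  ds <- gen_labeled_fragments(40, 40, motif_spec(effect = 5), seed = 12)
  fit <- ubi_cnn(ds, random_embedding(v, 10, seed = 13), v,
                 cnn = tiny_cnn(), train = tiny_train(epochs = 3))
  no_k <- gsub("K", "A", random_protein(100, seed = 14))
  expect_equal(nrow(predict_protein(fit, no_k)), 0)

  set.seed(15)
  prot <- paste(sample(c(AA_ALPHABET20, rep("K", 6)), 200, replace = TRUE),
                collapse = "")
  nk <- sum(strsplit(prot, "")[[1]] == "K")
  pred <- predict_protein(fit, prot)
  expect_equal(nrow(pred), nk)
  expect_true(all(pred$score > 0 & pred$score < 1))
  # threshold 1 predicts nothing (sigmoid scores are strictly below 1)
  expect_false(any(predict_protein(fit, prot, threshold = 1)$predicted))
})

test_that("model bundles round-trip through the plain-text format", {
  v <- build_vocab(2)
  ds <- gen_labeled_fragments(40, 40, motif_spec(effect = 5), seed = 16)
  fit <- ubi_cnn(ds, random_embedding(v, 10, seed = 17), v,
                 cnn = tiny_cnn(), train = tiny_train(epochs = 2))
  dir <- tempfile()
  save_ubi_cnn(fit, dir)
  back <- load_ubi_cnn(dir)
  frs <- random_fragments(10, seed = 18)
  expect_equal(predict_fragments(back, frs), predict_fragments(fit, frs),
               tolerance = 1e-6)
  expect_equal(back$window, fit$window)
})

test_that("predict method returns scores or class labels", {
  v <- build_vocab(2)
  ds <- gen_labeled_fragments(40, 40, motif_spec(effect = 5), seed = 19)
  fit <- ubi_cnn(ds, random_embedding(v, 10, seed = 20), v,
                 cnn = tiny_cnn(), train = tiny_train(epochs = 2))
  sc <- predict(fit, ds)
  expect_length(sc, 80)
  cl <- predict(fit, ds, type = "class")
  expect_s3_class(cl, "factor")
  expect_equal(as.character(cl), ifelse(sc >= 0.5, "positive", "negative"))
})
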