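#' Convolutional architecture configuration
#'
#' The classifier is an embedding lookup followed by `n_blocks` identical
#' blocks (1D convolution with `conv_filters` kernels of width
#' `kernel_size` and rectifier activation, max pooling of width
#' `pool_size`, dropout), a flatten, dense rectifier layers of sizes
#' `dense_sizes`, and a single logistic output unit. Convolutions use
#' valid padding, so a 30-token input shrinks 30 > 28 > 14 > 12 > 6 > 4 > 2
#' through the three default blocks.
#'
#' @param n_blocks number of conv/pool/dropout blocks, default 3.
#' @param conv_filters kernels per convolution, default 128.
#' @param kernel_size convolution width, default 3.
#' @param pool_size max-pooling width, default 2.
#' @param dropout_rate dropout after each pooling layer, default 0.5.
#' @param dense_sizes dense layer widths, default c(128, 64).
#' @return List of class `"cnn_config"`.
#' @export
cnn_config <- function(n_blocks = 3L, conv_filters = 128L, kernel_size = 3L,
                       pool_size = 2L, dropout_rate = 0.5,
                       dense_sizes = c(128L, 64L)) {
  stopifnot(n_blocks >= 1, conv_filters >= 1, kernel_size >= 1,
            pool_size >= 1, dropout_rate >= 0, dropout_rate < 1,
            all(dense_sizes >= 1))
  structure(list(n_blocks = as.integer(n_blocks),
                 conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 dropout_rate = dropout_rate,
                 dense_sizes = as.integer(dense_sizes)),
            class = "cnn_config")
}

#' Training configuration
#'
#' RMSprop on the binary cross-entropy loss. Defaults follow the training
#' recipe for the full-scale model: learning rate 0.001 with smoothing
#' constant 0.9, minibatches of 500, 120 epochs, Gaussian(0, 0.01)
#' initialization of conv/dense weights.
#'
#' @param learning_rate RMSprop step size, default 0.001.
#' @param rms_decay RMSprop smoothing constant (beta), default 0.9.
#' @param batch_size minibatch size, default 500.
#' @param epochs training epochs, default 120.
#' @param init_sigma sd of the Gaussian weight init, default 0.01.
#' @param seed RNG seed for init, shuffling and dropout.
#' @param freeze_embedding keep the transferred embedding fixed instead of
#'   fine-tuning it, default FALSE.
#' @return List of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 0.001, rms_decay = 0.9,
                         batch_size = 500L, epochs = 120L,
                         init_sigma = 0.01, seed = 1L,
                         freeze_embedding = FALSE) {
  stopifnot(learning_rate > 0, rms_decay > 0, rms_decay < 1,
            batch_size >= 1, epochs >= 1, init_sigma > 0)
  structure(list(learning_rate = learning_rate, rms_decay = rms_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), init_sigma = init_sigma,
                 seed = as.integer(seed),
                 freeze_embedding = isTRUE(freeze_embedding)),
            class = "train_config")
}

# sequence lengths through the conv stack; errors if a layer collapses
conv_lengths <- function(n_tokens, cnn) {
  len <- n_tokens
  for (b in seq_len(cnn$n_blocks)) {
    len <- len - cnn$kernel_size + 1L
    if (len < 1) stop("sequence too short for the configured conv stack")
    len <- len %/% cnn$pool_size
    if (len < 1) stop("sequence too short for the configured pool stack")
  }
  len
}

#' Build an (untrained) embedding-initialized classifier
#'
#' Assembles the network and initializes it: the embedding layer is set to
#' the supplied (pretrained or random) matrix exactly; every conv and
#' dense weight is Gaussian(0, `init_sigma`), all biases zero.
#'
#' @param embedding an `"embedding_matrix"` with one row per vocabulary
#'   token plus the pad row.
#' @param vocab the [build_vocab()] vocabulary the embedding indexes.
#' @param window fragment window length, default 31 (so 30 bigram tokens).
#' @param cnn a [cnn_config()].
#' @param train a [train_config()] (stored; used by [train_ubi_cnn()]).
#' @return Object of class `"ubi_cnn"` (untrained: empty history).
#' @export
build_ubi_cnn <- function(embedding, vocab, window = 31L,
                          cnn = cnn_config(), train = train_config()) {
  if (nrow(embedding) != vocab$pad_index) {
    stop("embedding has ", nrow(embedding), " rows but vocabulary needs ",
         vocab$pad_index)
  }
  n_tokens <- window - vocab$n + 1L
  conv_lengths(n_tokens, cnn)  # validate shapes
  set.seed(train$seed)
  D <- ncol(embedding)
  conv_W <- list(); conv_b <- list()
  cin <- D
  for (b in seq_len(cnn$n_blocks)) {
    conv_W[[b]] <- matrix(rnorm(cnn$kernel_size * cin * cnn$conv_filters,
                                0, train$init_sigma),
                          cnn$kernel_size * cin, cnn$conv_filters)
    conv_b[[b]] <- rep(0, cnn$conv_filters)
    cin <- cnn$conv_filters
  }
  flat <- conv_lengths(n_tokens, cnn) * cnn$conv_filters
  sizes <- c(flat, cnn$dense_sizes, 1L)
  dense_W <- list(); dense_b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    dense_W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], 0, train$init_sigma),
                           sizes[l], sizes[l + 1])
    dense_b[[l]] <- rep(0, sizes[l + 1])
  }
  params <- list(E = unname(unclass(embedding)[, , drop = FALSE]),
                 conv_W = conv_W, conv_b = conv_b,
                 dense_W = dense_W, dense_b = dense_b,
                 kernel = cnn$kernel_size, pool = cnn$pool_size)
  structure(list(params = params, cnn = cnn, train = train, vocab = vocab,
                 window = as.integer(window), history = numeric()),
            class = "ubi_cnn")
}

tokenize_fragments <- function(sequences, vocab, window) {
  lens <- nchar(sequences)
  if (any(lens != window)) {
    stop("fragment length mismatch: expected ", window, ", got ",
         lens[which(lens != window)[1]], " (fragment ",
         which(lens != window)[1], ")")
  }
  t(vapply(sequences, tokenize, integer(window - vocab$n + 1L),
           vocab = vocab, USE.NAMES = FALSE))
}

#' Fine-tune a classifier on labeled fragments
#'
#' Minimizes binary cross-entropy with RMSprop; dropout is active during
#' training only; the embedding layer is fine-tuned unless
#' `config$freeze_embedding`. Reproducible given `config$seed`
#' (single-threaded).
#'
#' @param model an (untrained or trained) `"ubi_cnn"`.
#' @param dataset labeled fragment data frame (`sequence`, `label`).
#' @param config a [train_config()]; defaults to the model's stored one.
#' @return The trained `"ubi_cnn"` with per-epoch loss in `$history`.
#' @export
train_ubi_cnn <- function(model, dataset, config = model$train) {
  if (nrow(dataset) == 0) stop("empty training dataset")
  y <- as.numeric(dataset$label == "positive")
  if (length(unique(y)) < 2) stop("training dataset must contain both classes")
  tokens <- tokenize_fragments(dataset$sequence, model$vocab, model$window)
  set.seed(config$seed)
  fit <- cnn_train_cpp(tokens, y, model$params,
                       epochs = config$epochs,
                       batch_size = config$batch_size,
                       lr = config$learning_rate,
                       rho = config$rms_decay,
                       dropout = model$cnn$dropout_rate,
                       freeze_embedding = config$freeze_embedding)
  model$params <- fit$params
  model$train <- config
  model$history <- c(model$history, fit$history)
  model
}

#' Fit the full ubiquitylation-site classifier
#'
#' Convenience front end: builds the embedding-initialized network
#' ([build_ubi_cnn()]) and fine-tunes it on the labeled fragments
#' ([train_ubi_cnn()]).
#'
#' @inheritParams build_ubi_cnn
#' @param dataset labeled fragment data frame with columns `sequence` and
#'   `label` (`"positive"`/`"negative"`).
#' @return A fitted object of class `"ubi_cnn"` with components `params`
#'   (weights), `cnn`, `train`, `vocab`, `window` and `history`
#'   (per-epoch training loss).
#' @examples
#' \donttest{
#' spec <- motif_spec(effect = 3)
#' ds <- gen_labeled_fragments(300, 300, spec, seed = 1)
#' vocab <- build_vocab(2)
#' emb <- random_embedding(vocab, 20, seed = 1)
#' fit <- ubi_cnn(ds, emb, vocab,
#'                train = train_config(epochs = 3, batch_size = 64))
#' head(predict(fit, ds))
#' }
#' @export
ubi_cnn <- function(dataset, embedding, vocab, window = 31L,
                    cnn = cnn_config(), train = train_config()) {
  model <- build_ubi_cnn(embedding, vocab, window = window, cnn = cnn,
                         train = train)
  train_ubi_cnn(model, dataset, train)
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y log p + (1 - y) log(1 - p))` with scores clipped to
#' `[eps, 1 - eps]` so the loss is always finite.
#'
#' @param labels 0/1 vector.
#' @param scores probability vector of the same length.
#' @param eps clipping constant, default 1e-7.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(labels, scores, eps = 1e-7) {
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  p <- pmin(pmax(scores, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Score fragments with a fitted classifier
#'
#' @param model a fitted `"ubi_cnn"`.
#' @param fragments fragment data frame or character vector of
#'   window-length sequences.
#' @param batch_size inference batch size (does not affect the scores).
#' @return Numeric vector of probabilities in (0, 1), one per fragment,
#'   in input order.
#' @export
predict_fragments <- function(model, fragments, batch_size = 500L) {
  seqs <- if (is.data.frame(fragments)) fragments$sequence else fragments
  if (length(seqs) == 0) return(numeric())
  tokens <- tokenize_fragments(seqs, model$vocab, model$window)
  as.numeric(cnn_predict_cpp(tokens, model$params, batch_size))
}

#' Predict ubiquitylation sites across a whole protein
#'
#' Extracts the X-padded window around every lysine, scores each, and
#' reports the 1-based positions whose score reaches `threshold`.
#'
#' @param model a fitted `"ubi_cnn"`.
#' @param protein a sequence string, or a one-row data frame with `id`
#'   and `sequence`.
#' @param threshold decision threshold, default 0.5.
#' @return Data frame with one row per lysine: `protein_id`, `position`,
#'   `score`, `predicted` (logical, `score >= threshold`).
#' @export
predict_protein <- function(model, protein, threshold = 0.5) {
  if (is.data.frame(protein)) {
    id <- protein$id[1]; seq <- protein$sequence[1]
  } else {
    id <- "protein"; seq <- protein
  }
  seq <- normalize_residues(seq, warn = FALSE)
  frags <- extract_fragments(seq, integer(), window = model$window,
                             protein_id = id)
  if (nrow(frags) == 0) {
    return(data.frame(protein_id = character(), position = integer(),
                      score = numeric(), predicted = logical()))
  }
  scores <- predict_fragments(model, frags)
  data.frame(protein_id = id, position = frags$center_position,
             score = scores, predicted = scores >= threshold,
             stringsAsFactors = FALSE)
}

#' @export
predict.ubi_cnn <- function(object, newdata, type = c("response", "class"),
                            threshold = 0.5, ...) {
  type <- match.arg(type)
  scores <- predict_fragments(object, newdata)
  if (type == "response") return(scores)
  factor(ifelse(scores >= threshold, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' @export
print.ubi_cnn <- function(x, ...) {
  cat("Ubiquitylation-site CNN (", x$vocab$n, "-gram embedding, dim ",
      ncol(x$params$E), ")\n", sep = "")
  cat(sprintf("  window %d -> %d tokens; %d conv block(s) x %d filters (kernel %d, pool %d)\n",
              x$window, x$window - x$vocab$n + 1L, x$cnn$n_blocks,
              x$cnn$conv_filters, x$cnn$kernel_size, x$cnn$pool_size))
  cat("  dense layers:", paste(c(x$cnn$dense_sizes, 1), collapse = " -> "), "\n")
  cat("  parameters:", format(n_parameters(x), big.mark = ","), "\n")
  if (length(x$history) > 0) {
    cat(sprintf("  trained %d epoch(s); final BCE %.4f\n",
                length(x$history), x$history[length(x$history)]))
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

#' @export
summary.ubi_cnn <- function(object, ...) {
  print(object)
  if (length(object$history) > 0) {
    cat("  loss trajectory (first/min/last): ",
        sprintf("%.4f / %.4f / %.4f\n", object$history[1],
                min(object$history), object$history[length(object$history)]))
  }
  invisible(object)
}

#' @export
coef.ubi_cnn <- function(object, ...) object$params

#' @export
plot.ubi_cnn <- function(x, ...) {
  if (length(x$history) == 0) stop("model has no training history")
  graphics::plot(seq_along(x$history), x$history, type = "l",
                 xlab = "epoch", ylab = "training BCE loss",
                 main = "Training loss", ...)
  invisible(x)
}

#' Total trainable parameter count
#'
#' @param model a `"ubi_cnn"`.
#' @return Integer: number of weights and biases, embedding included.
#' @export
n_parameters <- function(model) {
  p <- model$params
  length(p$E) +
    sum(vapply(p$conv_W, length, 1)) + sum(vapply(p$conv_b, length, 1)) +
    sum(vapply(p$dense_W, length, 1)) + sum(vapply(p$dense_b, length, 1))
}

#' Save / load a fitted model as a plain-text bundle
#'
#' The bundle directory holds `config.json` (architecture, training
#' config, window, vocab size), `vocabulary.tsv`, and one TSV per weight
#' tensor.
#'
#' @param model a `"ubi_cnn"`.
#' @param dir bundle directory (created if missing).
#' @return `dir` invisibly (save); the restored `"ubi_cnn"` (load).
#' @export
save_ubi_cnn <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(cnn = unclass(model$cnn), train = unclass(model$train),
              window = model$window, vocab_n = model$vocab$n,
              history = model$history)
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA),
             file.path(dir, "config.json"))
  writeLines(c(model$vocab$tokens, model$vocab$pad_token),
             file.path(dir, "vocabulary.tsv"))
  p <- model$params
  wm <- function(m, name) {
    write.table(m, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  wm(p$E, "embedding")
  for (i in seq_along(p$conv_W)) {
    wm(p$conv_W[[i]], paste0("conv_W", i)); wm(p$conv_b[[i]], paste0("conv_b", i))
  }
  for (i in seq_along(p$dense_W)) {
    wm(p$dense_W[[i]], paste0("dense_W", i)); wm(p$dense_b[[i]], paste0("dense_b", i))
  }
  invisible(dir)
}

#' @rdname save_ubi_cnn
#' @export
load_ubi_cnn <- function(dir) {
  cfg <- jsonlite::fromJSON(file.path(dir, "config.json"))
  vocab <- build_vocab(cfg$vocab_n)
  rm_ <- function(name) {
    as.matrix(read.delim(file.path(dir, paste0(name, ".tsv")), header = FALSE))
  }
  cnn <- do.call(cnn_config, as.list(cfg$cnn))
  train <- do.call(train_config, as.list(cfg$train))
  params <- list(E = unname(rm_("embedding")),
                 conv_W = lapply(seq_len(cnn$n_blocks),
                                 function(i) unname(rm_(paste0("conv_W", i)))),
                 conv_b = lapply(seq_len(cnn$n_blocks),
                                 function(i) as.numeric(rm_(paste0("conv_b", i)))),
                 dense_W = lapply(seq_len(length(cnn$dense_sizes) + 1L),
                                  function(i) unname(rm_(paste0("dense_W", i)))),
                 dense_b = lapply(seq_len(length(cnn$dense_sizes) + 1L),
                                  function(i) as.numeric(rm_(paste0("dense_b", i)))),
                 kernel = cnn$kernel_size, pool = cnn$pool_size)
  structure(list(params = params, cnn = cnn, train = train, vocab = vocab,
                 window = as.integer(cfg$window),
                 history = as.numeric(cfg$history)),
            class = "ubi_cnn")
}
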