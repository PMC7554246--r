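#' Build the n-gram token vocabulary
#'
#' All n-grams over the 20 standard residues in lexicographic order, plus
#' one reserved pad token (`X` repeated n times) to which every n-gram
#' containing `X` maps. For the default n = 2 this gives 400 bigrams plus
#' the pad token at index 401.
#'
#' @param n gram length, one of 1, 2, 3 (default 2).
#' @return Object of class `"bigram_vocab"`: list with `n`, `tokens`
#'   (character, length 20^n), `pad_token`, `pad_index` (= 20^n + 1) and
#'   `index` (named integer lookup over tokens and pad).
#' @export
build_vocab <- function(n = 2L) {
  if (!n %in% 1:3) stop("n must be 1, 2 or 3")
  grids <- rev(replicate(n, AA_ALPHABET20, simplify = FALSE))
  tokens <- do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
  tokens <- sort(tokens)
  pad_token <- strrep(AA_PAD, n)
  index <- setNames(seq_len(length(tokens) + 1L), c(tokens, pad_token))
  structure(list(n = as.integer(n), tokens = tokens, pad_token = pad_token,
                 pad_index = length(tokens) + 1L, index = index),
            class = "bigram_vocab")
}

#' @export
print.bigram_vocab <- function(x, ...) {
  cat(sprintf("%d-gram vocabulary: %d tokens + 1 pad token (%s)\n",
              x$n, length(x$tokens), x$pad_token))
  invisible(x)
}

#' Tokenize a residue string into overlapping n-gram indices
#'
#' Emits all `L - n + 1` overlapping n-grams in order; any gram containing
#' the pad symbol `X` maps to the vocabulary's pad index. A sequence
#' shorter than n yields an empty token vector.
#'
#' @param sequence normalized residue string.
#' @param vocab a [build_vocab()] vocabulary.
#' @return Integer vector of 1-based vocabulary indices.
#' @export
tokenize <- function(sequence, vocab) {
  L <- nchar(sequence)
  n <- vocab$n
  if (L < n) return(integer())
  grams <- substring(sequence, seq_len(L - n + 1L), seq_len(L - n + 1L) + n - 1L)
  idx <- vocab$index[grams]
  idx[is.na(idx)] <- vocab$pad_index  # grams containing X
  unname(idx)
}

#' Reconstruct a sequence from its overlapping token indices
#'
#' Inverse of [tokenize()] for pad-free inputs: concatenates the first
#' token with the last character of every following token.
#'
#' @param indices integer token indices.
#' @param vocab a [build_vocab()] vocabulary.
#' @return Residue string (empty for empty input).
#' @export
detokenize <- function(indices, vocab) {
  if (length(indices) == 0) return("")
  toks <- c(vocab$tokens, vocab$pad_token)[indices]
  paste0(toks[1], paste(substring(toks[-1], vocab$n, vocab$n), collapse = ""))
}

#' Enumerate skip-gram (center, context) training pairs
#'
#' For every token position i, one pair per position j != i with
#' |i - j| <= `context_window`. Pad tokens are skipped both as centers
#' and as contexts. For an X-free token sequence of length L with window
#' w and L > 2w the pair count has the closed form 2wL - w(w + 1).
#'
#' @param tokens integer token indices (from [tokenize()]).
#' @param context_window positive window half-width, default 2.
#' @param pad_index index treated as pad (skipped); `NA` to disable.
#' @return Two-column integer matrix (`center`, `context`) of token
#'   indices.
#' @export
skipgram_pairs <- function(tokens, context_window = 2L, pad_index = NA) {
  if (context_window < 1) stop("context_window must be >= 1")
  L <- length(tokens)
  if (L < 2) return(matrix(integer(), ncol = 2,
                           dimnames = list(NULL, c("center", "context"))))
  out <- vector("list", L)
  for (i in seq_len(L)) {
    if (!is.na(pad_index) && tokens[i] == pad_index) next
    js <- max(1L, i - context_window):min(L, i + context_window)
    js <- js[js != i]
    if (!is.na(pad_index)) js <- js[tokens[js] != pad_index]
    if (length(js) > 0) out[[i]] <- cbind(center = tokens[i], context = tokens[js])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- matrix(integer(), ncol = 2)
  colnames(res) <- c("center", "context")
  res
}

#' Skip-gram configuration
#'
#' @param embedding_dim embedding dimension (default 20, matching the
#'   classifier's 30 x 20 input; 200 is also accepted, see the package
#'   vignette).
#' @param context_window context half-width, default 2 (i.e. +/- 2).
#' @param negative_samples negative samples per positive pair, default 5.
#' @param epochs passes over the corpus, default 5.
#' @param learning_rate initial SGD step, default 0.025, decayed linearly
#'   to `min_learning_rate`.
#' @param min_learning_rate final step size, default 1e-4.
#' @return List of class `"skipgram_config"`.
#' @export
skipgram_config <- function(embedding_dim = 20L, context_window = 2L,
                            negative_samples = 5L, epochs = 5L,
                            learning_rate = 0.025, min_learning_rate = 1e-4) {
  stopifnot(embedding_dim >= 1, context_window >= 1, negative_samples >= 1,
            epochs >= 1, learning_rate > 0, min_learning_rate > 0)
  structure(list(embedding_dim = as.integer(embedding_dim),
                 context_window = as.integer(context_window),
                 negative_samples = as.integer(negative_samples),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 min_learning_rate = min_learning_rate),
            class = "skipgram_config")
}

#' Pretrain bigram embeddings by skip-gram with negative sampling
#'
#' Tokenizes every protein into overlapping n-grams and trains a
#' word2vec-style skip-gram model: each non-pad token predicts its
#' neighbours within the context window, against `negative_samples`
#' draws from a unigram^0.75 noise distribution. The input-side (hidden
#' layer) weight matrix is returned; it is the matrix transferred into
#' the classifier's embedding layer. Tokenizing each protein once over
#' all overlapping n-grams covers both frame offsets of the sequence.
#'
#' Deterministic given `seed` (single-threaded; all randomness from R's
#' RNG).
#'
#' @param proteins data frame with a `sequence` column (e.g. from
#'   [read_fasta()]), or a character vector of sequences.
#' @param vocab a [build_vocab()] vocabulary.
#' @param config a [skipgram_config()].
#' @param seed integer RNG seed.
#' @return Object of class `"embedding_matrix"`: numeric matrix of size
#'   (20^n + 1) x embedding_dim with token rownames (pad row last, kept
#'   at zero), and attributes `config` and `vocab_n`.
#' @export
train_skipgram <- function(proteins, vocab, config = skipgram_config(),
                           seed = 1L) {
  seqs <- if (is.data.frame(proteins)) proteins$sequence else proteins
  if (length(seqs) == 0) stop("empty corpus")
  token_seqs <- lapply(seqs, tokenize, vocab = vocab)
  token_seqs <- token_seqs[vapply(token_seqs, length, 1L) > 0]
  if (length(token_seqs) == 0) stop("corpus contains no tokenizable sequence")
  set.seed(seed)
  W <- sgns_train_cpp(token_seqs, vocab_size = vocab$pad_index,
                      pad_idx = vocab$pad_index,
                      dim = config$embedding_dim,
                      window = config$context_window,
                      negative = config$negative_samples,
                      epochs = config$epochs,
                      lr = config$learning_rate,
                      min_lr = config$min_learning_rate)
  rownames(W) <- c(vocab$tokens, vocab$pad_token)
  structure(W, class = c("embedding_matrix", class(W)),
            config = config, vocab_n = vocab$n, seed = seed)
}

#' Random embedding initialization
#'
#' Gaussian-initialized embedding of the same shape as a pretrained one;
#' the no-transfer baseline for comparing against skip-gram pretraining.
#'
#' @param vocab a [build_vocab()] vocabulary.
#' @param embedding_dim embedding width.
#' @param sigma Gaussian standard deviation, default 0.01.
#' @param seed RNG seed.
#' @return An `"embedding_matrix"` (pad row zero).
#' @export
random_embedding <- function(vocab, embedding_dim = 20L, sigma = 0.01,
                             seed = 1L) {
  set.seed(seed)
  W <- matrix(rnorm(vocab$pad_index * embedding_dim, 0, sigma),
              vocab$pad_index, embedding_dim)
  W[vocab$pad_index, ] <- 0
  rownames(W) <- c(vocab$tokens, vocab$pad_token)
  structure(W, class = c("embedding_matrix", class(W)),
            config = NULL, vocab_n = vocab$n, seed = seed)
}

#' Cosine similarity between token embedding rows
#'
#' @param emb an `"embedding_matrix"`.
#' @param a,b token strings or row indices.
#' @return Cosine similarity in [-1, 1] (0 if either vector is zero).
#' @export
embedding_cosine <- function(emb, a, b) {
  va <- emb[a, ]; vb <- emb[b, ]
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) return(0)
  sum(va * vb) / (na * nb)
}

#' Nearest neighbour of a token in embedding space
#'
#' @param emb an `"embedding_matrix"`.
#' @param token token string.
#' @param candidates tokens to search (default: all non-pad tokens except
#'   `token`).
#' @return The candidate with the highest cosine similarity to `token`.
#' @export
embedding_nearest <- function(emb, token, candidates = NULL) {
  all_tokens <- rownames(emb)
  if (is.null(candidates)) {
    candidates <- setdiff(all_tokens[-nrow(emb)], token)
  }
  sims <- vapply(candidates, function(ct) embedding_cosine(emb, token, ct),
                 numeric(1))
  candidates[which.max(sims)]
}

#' Read / write an embedding matrix as TSV (token + vector per row)
#'
#' @param emb an `"embedding_matrix"`.
#' @param path file path.
#' @return The embedding (read) or `path` invisibly (write).
#' @export
write_embedding <- function(emb, path) {
  df <- data.frame(token = rownames(emb), unclass(emb),
                   stringsAsFactors = FALSE, check.names = FALSE)
  colnames(df) <- c("token", paste0("d", seq_len(ncol(emb))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  # na.strings disabled: "NA" is the asparagine-alanine bigram token
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = character(0))
  W <- as.matrix(df[, -1, drop = FALSE])
  dimnames(W) <- list(df$token, NULL)
  n <- nchar(df$token[1])
  structure(W, class = c("embedding_matrix", class(W)),
            config = NULL, vocab_n = n)
}
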