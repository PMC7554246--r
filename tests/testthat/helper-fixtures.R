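# Shared fixtures, built in code at test time.

# random normalized protein of length L (no X unless asked)
random_protein <- function(L, seed = NULL, alphabet = AA_ALPHABET20) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# random 31-mer fragments with K center
random_fragments <- function(n, window = 31, seed = 1) {
  set.seed(seed)
  flank <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    left <- random_protein(flank)
    right <- random_protein(flank)
    paste0(left, "K", right)
  }, character(1))
}

as_fragment_df <- function(seqs, label = "positive") {
  data.frame(protein_id = sprintf("f%d", seq_along(seqs)),
             center_position = if (length(seqs)) (nchar(seqs[1]) + 1) / 2
                               else integer(),
             sequence = seqs,
             label = rep_len(label, length(seqs)),
             stringsAsFactors = FALSE)
}

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# reference greedy clustering, independent of the C++ implementation
greedy_cluster_oracle <- function(seqs, threshold) {
  reps <- integer()
  for (i in seq_along(seqs)) {
    ai <- strsplit(seqs[i], "")[[1]]
    hit <- FALSE
    for (r in reps) {
      ar <- strsplit(seqs[r], "")[[1]]
      ident <- sum(ai == ar & ai != "X") / length(ai)
      if (ident >= threshold) { hit <- TRUE; break }
    }
    if (!hit) reps <- c(reps, i)
  }
  reps
}

# tiny CNN configuration for fast classifier tests
tiny_cnn <- function() {
  cnn_config(n_blocks = 2, conv_filters = 8, kernel_size = 3, pool_size = 2,
             dropout_rate = 0.1, dense_sizes = c(12, 6))
}

tiny_train <- function(epochs = 5, seed = 1, ...) {
  train_config(epochs = epochs, batch_size = 32, learning_rate = 0.02,
               init_sigma = 0.05, seed = seed, ...)
}
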