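test_that("read_fasta parses, joins wrapped lines and normalizes residues", {
  p1 <- write_tmp_fasta(c(">p1", "MKV"))
  df <- read_fasta(p1)
  expect_equal(df$id, "p1")
  expect_equal(df$sequence, "MKV")

  p2 <- write_tmp_fasta(c(">p1 some description", "MK", "VK"))
  df2 <- read_fasta(p2)
  expect_equal(df2$sequence, "MKVK")
  expect_equal(df2$description, "some description")

  p3 <- write_tmp_fasta(c(">p1", "mkuv"))
  expect_warning(df3 <- read_fasta(p3), "non-standard")
  expect_equal(df3$sequence, "MKXV")
})

test_that("read_fasta rejects empty records", {
  path <- write_tmp_fasta(c(">a", "MKV", ">empty", "", ">b", "KK"))
  expect_error(read_fasta(path), "empty")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("fragment extraction pads with X and centers on K", {
  # single-residue protein: all flanks are padding
  f <- extract_fragments("K", sites = 1, window = 31)
  expect_equal(nrow(f), 1)
  expect_equal(f$sequence, paste0(strrep("X", 15), "K", strrep("X", 15)))
  expect_equal(f$label, "positive")

  # exactly window-length protein, K at the center: no padding at all
  seq31 <- paste0(random_protein(15, seed = 4,
                                 alphabet = setdiff(AA_ALPHABET20, "K")),
                  "K",
                  random_protein(15, alphabet = setdiff(AA_ALPHABET20, "K")))
  f2 <- extract_fragments(seq31, sites = 16, window = 31)
  expect_equal(f2$sequence, seq31)

  # K near the end: left flank partially real, right flank all padding
  f3 <- extract_fragments("ACDK", sites = integer(), window = 31)
  expect_equal(f3$sequence, paste0(strrep("X", 12), "ACDK", strrep("X", 15)))
  expect_equal(f3$label, "negative")
  expect_equal(nchar(f3$sequence), 31)
  expect_equal(substr(f3$sequence, 16, 16), "K")
})

test_that("every K yields one fragment with the stated length and center", {
  set.seed(7)
  for (i in 1:10) {
    seq <- random_protein(sample(31:120, 1))
    ks <- gregexpr("K", seq)[[1]]
    nk <- if (ks[1] == -1) 0 else length(ks)
    f <- extract_fragments(seq, sites = integer(), window = 31)
    expect_equal(nrow(f), nk)
    if (nk > 0) {
      expect_true(all(nchar(f$sequence) == 31))
      expect_true(all(substr(f$sequence, 16, 16) == "K"))
    }
  }
})

test_that("annotated positions that do not hold K are reported and skipped", {
  expect_warning(f <- extract_fragments("AKA", sites = c(1, 2), window = 3),
                 "do not hold K")
  expect_equal(f$label, "positive")  # position 2 kept
  expect_equal(f$center_position, 2)
})

test_that("greedy clustering keeps and drops by Hamming identity", {
  frags <- as_fragment_df(rep(random_fragments(1, seed = 1), 2))
  expect_equal(nrow(cluster_reduce(frags, 0.30)), 1)

  # one mismatch out of 31: identity 30/31, far above 0.30
  a <- random_fragments(1, seed = 2)
  b <- a
  substr(b, 1, 1) <- if (substr(a, 1, 1) == "A") "C" else "A"
  expect_equal(nrow(cluster_reduce(as_fragment_df(c(a, b)), 0.30)), 1)

  # agree at only 5 of 31 positions: identity ~0.161 < 0.30
  a <- paste0(strrep("A", 15), "K", strrep("A", 15))
  b <- paste0(strrep("C", 13), "AA", "K", "AA", strrep("C", 13))
  expect_equal(sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]]), 5)
  expect_equal(nrow(cluster_reduce(as_fragment_df(c(a, b)), 0.30)), 2)

  # X never counts as a match, even against X
  allx <- paste0(strrep("X", 15), "K", strrep("X", 15))
  expect_equal(nrow(cluster_reduce(as_fragment_df(rep(allx, 2)), 0.30)), 2)

  expect_error(cluster_reduce(as_fragment_df(c("AKA", "AKAAA")), 0.3), "length")
  expect_error(cluster_reduce(as_fragment_df("AKA"), 0), "identity_threshold")
})

test_that("clustering matches a reference implementation and is idempotent", {
  set.seed(11)
  # random fragments plus planted near-duplicates
  base <- random_fragments(30, seed = 12)
  near <- vapply(base[1:10], function(s) {
    p <- sample(setdiff(1:31, 16), 3)
    ch <- strsplit(s, "")[[1]]
    ch[p] <- sample(AA_ALPHABET20, 3, replace = TRUE)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  seqs <- sample(c(base, near))
  for (thr in c(0.30, 0.7, 0.95)) {
    kept <- cluster_reduce(as_fragment_df(seqs), thr)
    expect_equal(kept$sequence, seqs[greedy_cluster_oracle(seqs, thr)],
                 info = paste("threshold", thr))
    again <- cluster_reduce(kept, thr)
    expect_equal(again$sequence, kept$sequence)
  }
})

test_that("balance_and_split balances, splits and reproduces from the seed", {
  pos <- as_fragment_df(random_fragments(350, seed = 1), "positive")
  neg <- as_fragment_df(random_fragments(1000, seed = 2), "negative")
  sp <- balance_and_split(pos, neg, test_size = 150, seed = 9)
  expect_equal(nrow(sp$train) + nrow(sp$test), 700)
  expect_equal(nrow(sp$test), 150)
  expect_equal(nrow(sp$train), 550)
  # balanced within 1 in both parts
  for (part in list(sp$train, sp$test)) {
    expect_lte(abs(sum(part$label == "positive") -
                   sum(part$label == "negative")), 1)
  }
  # disjoint and exhaustive over the balanced set
  expect_equal(length(intersect(
    paste(sp$train$protein_id, sp$train$label),
    paste(sp$test$protein_id, sp$test$label))), 0)

  sp2 <- balance_and_split(pos, neg, test_size = 150, seed = 9)
  expect_identical(sp, sp2)

  expect_error(balance_and_split(neg, pos, 10, 1), "fewer negatives")
  expect_error(balance_and_split(pos, neg, 700, 1), "test_size")
})

test_that("build_dataset pipeline runs end to end on synthetic annotations", {
  sim <- gen_annotated_proteins(n_proteins = 25, mean_length = 150,
                                spec = motif_spec(effect = 3), seed = 3)
  sp <- suppressWarnings(
    build_dataset(sim$proteins, sim$sites, test_size = 10, seed = 5))
  expect_s3_class(sp, "dataset_split")
  expect_true(all(nchar(sp$train$sequence) == 31))
  expect_true(all(substr(sp$test$sequence, 16, 16) == "K"))
})

test_that("fragment and site tables round-trip through TSV", {
  frags <- as_fragment_df(random_fragments(5, seed = 3))
  path <- tempfile(fileext = ".tsv")
  write_fragments(frags, path)
  expect_equal(read_fragments(path), frags)

  sites <- data.frame(protein_id = c("a", "b"), position = c(3L, 7L))
  sp <- tempfile(fileext = ".tsv")
  write_sites(sites, sp)
  expect_equal(read_sites(sp), sites)
})
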