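#' Read protein sequences from a FASTA file
#'
#' Parses a standard FASTA file (via Biostrings) and normalizes every
#' sequence to the 21-symbol alphabet: lowercase is raised and residues
#' outside the 20 standard amino acids (B, J, O, U, Z, `*`, `-`, ...) are
#' replaced by `X` with a warning.
#'
#' @param path path to a FASTA file.
#' @return A data frame with columns `id` (first whitespace-delimited word
#'   of the header), `description` (remainder of the header) and
#'   `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("FASTA file contains no records: ", path)
  headers <- names(set)
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) {
    stop("FASTA record with empty sequence: ",
         headers[which(!nzchar(seqs))[1]])
  }
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  data.frame(id = ids, description = desc,
             sequence = normalize_residues(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins data frame with columns `id` and `sequence` (and
#'   optionally `description`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::BStringSet(proteins$sequence)
  desc <- proteins$description
  names(set) <- if (!is.null(desc) && any(nzchar(desc))) {
    trimws(paste(proteins$id, desc))
  } else {
    proteins$id
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a site-annotation table
#'
#' The table is tab-separated with a header line and columns
#' `protein_id` and `position` (1-based residue index of the annotated
#' lysine in its parent protein).
#'
#' @param path path to the TSV file.
#' @return Data frame with columns `protein_id` (character) and
#'   `position` (integer).
#' @export
read_sites <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "position") %in% names(df))) {
    stop("sites table must have columns 'protein_id' and 'position'")
  }
  df$protein_id <- as.character(df$protein_id)
  df$position <- as.integer(df$position)
  df[, c("protein_id", "position")]
}

#' Write a site-annotation table
#' @param sites data frame with columns `protein_id`, `position`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  write.table(sites[, c("protein_id", "position")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract lysine-centered fragments from one protein
#'
#' Slides a window of odd length `window` over the sequence and cuts one
#' fragment per lysine: listed positions become positive fragments, every
#' other K becomes a negative fragment. Flanks extending past either
#' terminus are padded with the pseudo-residue `X`, so each fragment has
#' exactly `(window - 1) / 2` characters on each side of the central K.
#'
#' Site positions are 1-based. A listed position whose residue is not K is
#' reported with a warning and skipped.
#'
#' @param sequence residue string (normalized; see [normalize_residues()]).
#' @param sites integer vector of 1-based positions annotated as modified.
#' @param window odd fragment length, default 31.
#' @param protein_id identifier carried into the output.
#' @return A fragment data frame: `protein_id`, `center_position`,
#'   `sequence`, `label` (`"positive"`/`"negative"`).
#' @export
extract_fragments <- function(sequence, sites = integer(), window = 31L,
                              protein_id = "protein") {
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  ch <- strsplit(sequence, "")[[1]]
  L <- length(ch)
  sites <- unique(as.integer(sites))
  bad <- sites[sites < 1 | sites > L | ch[pmin(pmax(sites, 1), L)] != "K"]
  if (length(bad) > 0) {
    warning(sprintf("%s: %d annotated position(s) (%s) do not hold K; skipped",
                    protein_id, length(bad), paste(bad, collapse = ",")))
    sites <- setdiff(sites, bad)
  }
  centers <- which(ch == "K")
  if (length(centers) == 0) return(empty_fragments())
  flank <- (window - 1L) %/% 2L
  padded <- c(rep(AA_PAD, flank), ch, rep(AA_PAD, flank))
  frags <- vapply(centers, function(p) {
    paste(padded[p:(p + 2L * flank)], collapse = "")
  }, character(1))
  data.frame(protein_id = protein_id,
             center_position = centers,
             sequence = frags,
             label = ifelse(centers %in% sites, "positive", "negative"),
             stringsAsFactors = FALSE)
}

empty_fragments <- function() {
  data.frame(protein_id = character(), center_position = integer(),
             sequence = character(), label = character(),
             stringsAsFactors = FALSE)
}

#' Extract fragments for a whole protein set
#'
#' Applies [extract_fragments()] to every protein. By default only
#' proteins that carry at least one annotated site contribute negative
#' fragments (`negatives_from = "annotated"`); with
#' `negatives_from = "all"` every K in every input protein lacking an
#' annotation becomes a negative.
#'
#' @param proteins data frame from [read_fasta()].
#' @param sites data frame from [read_sites()].
#' @param window odd fragment length.
#' @param negatives_from `"annotated"` or `"all"`.
#' @return A fragment data frame (see [extract_fragments()]).
#' @export
extract_all_fragments <- function(proteins, sites, window = 31L,
                                  negatives_from = c("annotated", "all")) {
  negatives_from <- match.arg(negatives_from)
  keep <- if (negatives_from == "annotated") {
    proteins$id %in% sites$protein_id
  } else {
    rep(TRUE, nrow(proteins))
  }
  out <- lapply(which(keep), function(i) {
    extract_fragments(proteins$sequence[i],
                      sites$position[sites$protein_id == proteins$id[i]],
                      window = window, protein_id = proteins$id[i])
  })
  do.call(rbind, c(out, list(empty_fragments())))
}

#' Greedy identity-based redundancy reduction
#'
#' Clusters equal-length fragments by greedy incremental assignment:
#' fragments are processed in input order, each joining the first existing
#' cluster whose representative shares at least `identity_threshold`
#' pairwise identity, otherwise founding a new cluster. Identity is the
#' fraction of exactly matching columns (for equal-length ungapped
#' fragments this is Hamming identity); the pad symbol `X` never counts as
#' a match. Cluster representatives are returned.
#'
#' This is a self-contained reimplementation of the usual greedy
#' redundancy-reduction strategy (as in CD-HIT); exact parity with
#' external tools is not claimed.
#'
#' @param fragments fragment data frame (uniform `sequence` length).
#' @param identity_threshold fraction in (0, 1], default 0.30.
#' @return The subset of `fragments` kept as representatives, with an
#'   attribute `"clusters"` giving each input fragment's cluster id.
#' @export
cluster_reduce <- function(fragments, identity_threshold = 0.30) {
  if (identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must be in (0, 1]")
  }
  if (nrow(fragments) == 0) return(fragments)
  lens <- nchar(fragments$sequence)
  if (length(unique(lens)) != 1) stop("fragments must all have the same length")
  codes <- residue_codes(fragments$sequence)
  res <- greedy_cluster_cpp(codes, identity_threshold, pad_code = 21L)
  out <- fragments[res$representatives, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "clusters") <- res$cluster
  out
}

#' Balance classes and split into train / test sets
#'
#' Subsamples the negatives without replacement down to the number of
#' positives, then holds out `test_size` fragments uniformly at random,
#' stratified by label, as the independent test set. Fully reproducible
#' from `seed`.
#'
#' @param positives,negatives fragment data frames.
#' @param test_size number of fragments to hold out.
#' @param seed integer RNG seed.
#' @return A list of class `"dataset_split"` with elements `train`,
#'   `test` (fragment data frames) and `seed`.
#' @export
balance_and_split <- function(positives, negatives, test_size, seed) {
  np <- nrow(positives); nn <- nrow(negatives)
  if (nn < np) stop("fewer negatives (", nn, ") than positives (", np, ")")
  if (test_size >= 2 * np) stop("test_size must be smaller than the balanced set")
  set.seed(seed)
  neg <- negatives[sample.int(nn, np), , drop = FALSE]
  n_test_pos <- test_size %/% 2L
  n_test_neg <- test_size - n_test_pos
  itp <- sample.int(np, n_test_pos)
  itn <- sample.int(np, n_test_neg)
  test <- rbind(positives[itp, , drop = FALSE], neg[itn, , drop = FALSE])
  train <- rbind(positives[-itp, , drop = FALSE], neg[-itn, , drop = FALSE])
  rownames(test) <- rownames(train) <- NULL
  structure(list(train = train, test = test, seed = seed),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("Dataset split (seed ", x$seed, ")\n", sep = "")
  for (part in c("train", "test")) {
    d <- x[[part]]
    cat(sprintf("  %-5s %5d fragments (%d positive / %d negative)\n", part,
                nrow(d), sum(d$label == "positive"),
                sum(d$label == "negative")))
  }
  invisible(x)
}

#' Build a labeled fragment dataset from FASTA + sites
#'
#' Full preprocessing pipeline: extract lysine-centered fragments, reduce
#' redundancy by greedy identity clustering, balance the classes and split
#' off an independent test set.
#'
#' @param proteins data frame from [read_fasta()].
#' @param sites data frame from [read_sites()].
#' @param window odd fragment length, default 31.
#' @param identity_threshold clustering threshold (`NULL` to skip).
#' @param cluster_by `"joint"` clusters positives and negatives together
#'   (default); `"class"` clusters each label separately.
#' @param test_size held-out fragment count.
#' @param seed RNG seed.
#' @param negatives_from see [extract_all_fragments()].
#' @return A `"dataset_split"` (see [balance_and_split()]).
#' @export
build_dataset <- function(proteins, sites, window = 31L,
                          identity_threshold = 0.30,
                          cluster_by = c("joint", "class"),
                          test_size = 1500L, seed = 1L,
                          negatives_from = "annotated") {
  cluster_by <- match.arg(cluster_by)
  frags <- extract_all_fragments(proteins, sites, window = window,
                                 negatives_from = negatives_from)
  if (!is.null(identity_threshold)) {
    if (cluster_by == "joint") {
      frags <- cluster_reduce(frags, identity_threshold)
    } else {
      frags <- rbind(
        cluster_reduce(frags[frags$label == "positive", ], identity_threshold),
        cluster_reduce(frags[frags$label == "negative", ], identity_threshold))
    }
  }
  balance_and_split(frags[frags$label == "positive", , drop = FALSE],
                    frags[frags$label == "negative", , drop = FALSE],
                    test_size = test_size, seed = seed)
}

#' Read / write a fragment dataset as TSV
#'
#' Columns: `protein_id`, `center_position`, `sequence`, `label`.
#'
#' @param fragments fragment data frame.
#' @param path file path.
#' @return The data frame (read) or `path` invisibly (write).
#' @export
write_fragments <- function(fragments, path) {
  write.table(fragments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "center_position", "sequence", "label")
  if (!all(need %in% names(df))) {
    stop("fragment table must have columns ", paste(need, collapse = ", "))
  }
  df[, need]
}
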