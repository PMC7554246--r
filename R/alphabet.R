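#' The 20 standard amino acids, alphabetically by one-letter code
#'
#' Canonical residue order used for all composition vectors and count
#' matrices in this package.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Pad / unknown residue symbol
#'
#' Flanks that fall outside the parent protein, and any non-standard input
#' residue (B, J, O, U, Z, `*`, `-`, ...), are represented by `X`.
#'
#' @format Character scalar.
#' @export
AA_PAD <- "X"

#' Normalize a residue string to the 21-symbol alphabet
#'
#' Uppercases the input and maps every character outside the 20 standard
#' amino acids to the pad symbol `X`.
#'
#' @param x character vector of residue strings.
#' @param warn warn when non-standard residues are replaced?
#' @return Character vector of the same length, over `A..Y` plus `X`.
#' @export
normalize_residues <- function(x, warn = TRUE) {
  x <- toupper(x)
  bad <- gsub(paste0("[", paste(c(AA_ALPHABET20, AA_PAD), collapse = ""), "]"),
              "", x)
  nbad <- sum(nchar(bad))
  if (nbad > 0) {
    if (warn) {
      warning(sprintf("replaced %d non-standard residue(s) (%s) with %s",
                      nbad,
                      paste(unique(strsplit(paste(bad, collapse = ""), "")[[1]]),
                            collapse = ""),
                      AA_PAD))
    }
    x <- vapply(x, function(s) {
      ch <- strsplit(s, "")[[1]]
      ch[!(ch %in% c(AA_ALPHABET20, AA_PAD))] <- AA_PAD
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  x
}

# integer codes 1..20 for residues, 21 for X; used by the clustering core
residue_codes <- function(seqs) {
  lut <- setNames(seq_len(21), c(AA_ALPHABET20, AA_PAD))
  t(vapply(strsplit(seqs, ""), function(ch) unname(lut[ch]),
           integer(nchar(seqs[1]))))
}
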