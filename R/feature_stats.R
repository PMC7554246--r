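#' Amino-acid composition of a fragment set
#'
#' Counts each of the 20 standard residues over all fragments and divides
#' by the total residue count N = window x n_fragments. The pad symbol
#' `X` contributes to N (the denominator is the full fragment length) but
#' is not reported as a residue, so the 20 frequencies sum to at most 1,
#' with equality exactly when no `X` occurs.
#'
#' @param fragments fragment data frame or character vector of
#'   equal-length residue strings.
#' @return Object of class `"aac"`: list with `frequencies` (named
#'   20-vector), `counts`, `n_total`.
#' @export
compute_aac <- function(fragments) {
  seqs <- fragment_sequences(fragments)
  ch <- unlist(strsplit(seqs, ""), use.names = FALSE)
  counts <- table(factor(ch, levels = AA_ALPHABET20))
  counts <- setNames(as.integer(counts), AA_ALPHABET20)
  n_total <- length(ch)
  structure(list(frequencies = counts / n_total, counts = counts,
                 n_total = n_total),
            class = "aac")
}

#' @export
print.aac <- function(x, ...) {
  cat("Amino-acid composition over", x$n_total, "residues\n")
  print(round(x$frequencies, 4))
  invisible(x)
}

fragment_sequences <- function(fragments) {
  seqs <- if (is.data.frame(fragments)) fragments$sequence else fragments
  if (length(seqs) == 0) stop("empty fragment set")
  if (length(unique(nchar(seqs))) != 1) stop("fragments must have equal length")
  seqs
}

#' Adjacent-dipeptide (amino-acid pairwise) composition
#'
#' Counts the `window - 1` overlapping ordered adjacent residue pairs of
#' every fragment. Pairs containing the pad symbol `X` are excluded from
#' both numerator and denominator, so the reported frequencies sum to 1
#' whenever any pair was countable.
#'
#' @inheritParams compute_aac
#' @return Object of class `"aapc"`: list with `frequencies` (20 x 20
#'   matrix, rows = first residue), `counts`, `counted_pairs`.
#' @export
compute_aapc <- function(fragments) {
  seqs <- fragment_sequences(fragments)
  if (nchar(seqs[1]) < 2) stop("fragments must have length >= 2")
  ch <- strsplit(seqs, "")
  first <- unlist(lapply(ch, function(s) s[-length(s)]), use.names = FALSE)
  second <- unlist(lapply(ch, function(s) s[-1]), use.names = FALSE)
  ok <- first != AA_PAD & second != AA_PAD
  counts <- table(factor(first[ok], levels = AA_ALPHABET20),
                  factor(second[ok], levels = AA_ALPHABET20))
  counts <- matrix(as.integer(counts), 20, 20,
                   dimnames = list(AA_ALPHABET20, AA_ALPHABET20))
  n <- sum(ok)
  if (n == 0) warning("no countable dipeptides (all pairs touch X)")
  freq <- if (n > 0) counts / n else counts * 0
  structure(list(frequencies = freq, counts = counts, counted_pairs = n),
            class = "aapc")
}

#' Positional residue-count matrix
#'
#' Tallies, for each residue (20 standard + `X`) and each window
#' position, how many fragments carry that residue at that position.
#' Every column sums to the number of fragments. Columns are labeled by
#' offset from the central lysine: -15 ... -1, 0, +1 ... +15 for the
#' default window of 31.
#'
#' @inheritParams compute_aac
#' @return Object of class `"pwm_counts"`: list with `counts` (21 x
#'   window integer matrix), `n_fragments`, `offsets`.
#' @export
compute_pwm <- function(fragments) {
  seqs <- fragment_sequences(fragments)
  window <- nchar(seqs[1])
  mat <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                nrow = length(seqs), ncol = window, byrow = TRUE)
  levels21 <- c(AA_ALPHABET20, AA_PAD)
  counts <- vapply(seq_len(window), function(j) {
    as.integer(table(factor(mat[, j], levels = levels21)))
  }, integer(21))
  offsets <- seq_len(window) - (window + 1L) %/% 2L
  dimnames(counts) <- list(levels21, offset_labels(offsets))
  structure(list(counts = counts, n_fragments = length(seqs),
                 offsets = offsets),
            class = "pwm_counts")
}

offset_labels <- function(offsets) {
  ifelse(offsets > 0, paste0("+", offsets), as.character(offsets))
}

#' Elementwise log-ratio of two non-negative tables
#'
#' Computes `ln((pos + pseudocount) / (neg + pseudocount))` elementwise.
#' Used both for the dipeptide contrast (on pooled dipeptide counts or
#' frequencies) and for the positional contrast M (on pooled positional
#' counts). The pseudocount keeps every entry finite; the result is
#' antisymmetric under swapping the two tables.
#'
#' @param pos_table,neg_table numeric matrices or vectors of identical
#'   shape (counts or frequencies); `"aapc"` / `"pwm_counts"` objects are
#'   accepted and their counts used.
#' @param pseudocount positive smoothing constant, default 1 (Laplace).
#' @return Numeric matrix of the same shape, with attribute
#'   `"pseudocount"`.
#' @export
log_ratio <- function(pos_table, neg_table, pseudocount = 1) {
  pos <- extract_table(pos_table)
  neg <- extract_table(neg_table)
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (!identical(dim(pos), dim(neg)) || length(pos) != length(neg)) {
    stop("tables must have identical shape")
  }
  out <- log((pos + pseudocount) / (neg + pseudocount))
  attr(out, "pseudocount") <- pseudocount
  out
}

extract_table <- function(x) {
  if (inherits(x, "aapc")) return(x$counts)
  if (inherits(x, "pwm_counts")) return(x$counts)
  if (inherits(x, "aac")) return(x$counts)
  x
}

#' Two-sample logo statistics
#'
#' For every residue x non-center position, performs a two-proportion
#' z-test (pooled variance, two-sided) of the residue's occurrence
#' frequency in the positive vs. the negative fragment set. Entries with
#' (optionally corrected) p-value at or below `alpha` are flagged
#' significant; direction is the sign of the frequency difference. The
#' center column is excluded (it is K by construction).
#'
#' @param pos,neg fragment data frames or character vectors, same length.
#' @param alpha significance level in (0, 1], default 0.05.
#' @param correction `"none"` (default) or `"bonferroni"` across the
#'   20 x (window - 1) tests.
#' @return Object of class `"logo_stats"`: data frame with columns
#'   `residue`, `offset`, `freq_pos`, `freq_neg`, `z`, `p`, `direction`,
#'   `significant`; attributes `alpha`, `correction`, `n_pos`, `n_neg`.
#' @export
two_sample_logo <- function(pos, neg, alpha = 0.05,
                            correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  pwm_p <- compute_pwm(pos)
  pwm_n <- compute_pwm(neg)
  if (!identical(pwm_p$offsets, pwm_n$offsets)) {
    stop("positive and negative fragments must have the same length")
  }
  keep <- pwm_p$offsets != 0L
  n1 <- pwm_p$n_fragments
  n2 <- pwm_n$n_fragments
  c1 <- pwm_p$counts[AA_ALPHABET20, keep, drop = FALSE]
  c2 <- pwm_n$counts[AA_ALPHABET20, keep, drop = FALSE]
  p1 <- c1 / n1
  p2 <- c2 / n2
  pooled <- (c1 + c2) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (p1 - p2) / se, 0)
  p <- 2 * pnorm(-abs(z))
  padj <- if (correction == "bonferroni") pmin(1, p * length(p)) else p
  out <- data.frame(
    residue = rep(AA_ALPHABET20, times = sum(keep)),
    offset = rep(pwm_p$offsets[keep], each = 20L),
    freq_pos = as.vector(p1), freq_neg = as.vector(p2),
    z = as.vector(z), p = as.vector(p),
    direction = ifelse(as.vector(p1) >= as.vector(p2), "enriched", "depleted"),
    significant = as.vector(padj) <= alpha,
    stringsAsFactors = FALSE)
  structure(out, class = c("logo_stats", "data.frame"),
            alpha = alpha, correction = correction, n_pos = n1, n_neg = n2)
}

#' @export
print.logo_stats <- function(x, ...) {
  sig <- x[x$significant, , drop = FALSE]
  cat(sprintf("Two-sample logo: %d of %d (residue, position) cells significant at alpha = %g (%s)\n",
              nrow(sig), nrow(x), attr(x, "alpha"), attr(x, "correction")))
  if (nrow(sig) > 0) {
    sig <- sig[order(sig$p), , drop = FALSE]
    print(head(as.data.frame(sig), 10))
  }
  invisible(x)
}

#' Heatmap of a positional or dipeptide log-ratio matrix
#'
#' Simple base-graphics rendering: blue cells are enriched in the
#' positive set, red cells depleted.
#'
#' @param m matrix from [log_ratio()].
#' @param main plot title.
#' @return Invisibly, `m`.
#' @export
plot_log_ratio <- function(m, main = "log-ratio") {
  pal <- grDevices::colorRampPalette(c("red", "white", "blue"))(101)
  lim <- max(abs(m), 1e-9)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ]),
                  col = pal, zlim = c(-lim, lim), axes = FALSE,
                  xlab = "", ylab = "", main = main)
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.6)
  graphics::axis(2, seq_len(nrow(m)), rev(rownames(m)), las = 1, cex.axis = 0.6)
  invisible(m)
}

#' Write the comparative feature statistics of a labeled dataset
#'
#' Computes AAC for both classes, the dipeptide log-ratio, the positional
#' log-ratio and the two-sample logo table, writing each as TSV to
#' `out_dir`.
#'
#' @param fragments labeled fragment data frame.
#' @param out_dir output directory (created if missing).
#' @param alpha significance level for the logo test.
#' @param pseudocount smoothing for the log-ratios.
#' @param correction multiple-testing correction for the logo test.
#' @return Invisibly, a list with the four computed objects.
#' @export
feature_report <- function(fragments, out_dir, alpha = 0.05,
                           pseudocount = 1, correction = "none") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pos <- fragments[fragments$label == "positive", , drop = FALSE]
  neg <- fragments[fragments$label == "negative", , drop = FALSE]
  aac_p <- compute_aac(pos); aac_n <- compute_aac(neg)
  aapc_lr <- log_ratio(compute_aapc(pos), compute_aapc(neg), pseudocount)
  pwm_lr <- log_ratio(compute_pwm(pos), compute_pwm(neg), pseudocount)
  logo <- two_sample_logo(pos, neg, alpha = alpha, correction = correction)

  write.table(data.frame(residue = AA_ALPHABET20,
                         freq_pos = as.vector(aac_p$frequencies),
                         freq_neg = as.vector(aac_n$frequencies)),
              file.path(out_dir, "aac.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(aapc_lr, file.path(out_dir, "aapc_logratio.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  write.table(pwm_lr, file.path(out_dir, "pwm_logratio.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  write.table(as.data.frame(logo), file.path(out_dir, "logo_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(aac_pos = aac_p, aac_neg = aac_n, aapc_logratio = aapc_lr,
                 pwm_logratio = pwm_lr, logo = logo))
}
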