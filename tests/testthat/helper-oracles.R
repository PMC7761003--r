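# Independent oracles used to check package computations.  Each deliberately
# recomputes the quantity from first principles, not through the code path it
# verifies.

# Pearson r by the direct product-moment formula.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Hypergeometric upper tail P(X >= k) by explicit pmf summation with choose().
oracle_hyper_upper <- function(k, N, a, b) {
  ks <- k:min(a, b)
  sum(choose(a, ks) * choose(N - a, b - ks)) / choose(N, b)
}

# Benjamini-Hochberg step-up by the textbook definition:
# padj(i) = min_{j >= i} p(j) * m / j on the sorted p-values.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- rev(cummin(rev(sorted * m / seq_len(m))))
  pmin(adj, 1)[order(o)]
}

# Best local-alignment score by exhaustive enumeration of every start cell
# and every monotone operation path, with affine gap costs.  Exponential;
# only usable on very short sequences.
oracle_local_score <- function(q, s, match = 2, mismatch = -3,
                               gap_open = -5, gap_extend = -2) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  best <- 0
  rec <- function(i, j, acc, state) {
    if (acc > best) best <<- acc
    if (i > n && j > m) return(invisible())
    if (i <= n && j <= m) {
      sub <- if (qc[i] == sc[j] && qc[i] != "N") match else mismatch
      rec(i + 1, j + 1, acc + sub, 0L)
    }
    if (i <= n) rec(i + 1, j, acc + if (state == 1L) gap_extend else
      gap_open + gap_extend, 1L)
    if (j <= m) rec(i, j + 1, acc + if (state == 2L) gap_extend else
      gap_open + gap_extend, 2L)
  }
  for (i in seq_len(n)) for (j in seq_len(m)) rec(i, j, 0, 0L)
  best
}

# Reference local alignment score from Biostrings (independent implementation
# of the same scoring convention: a gap of length L costs opening + L*ext).
oracle_biostrings_score <- function(q, s, match = 2, mismatch = -3,
                                    gap_open = 5, gap_extend = 2) {
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    q, s, type = "local", substitutionMatrix = sub,
    gapOpening = gap_open, gapExtension = gap_extend))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# A small well-formed DEG data.frame.
make_deg <- function(ids, lfc, p, padj = bh_adjust(p)) {
  data.frame(gene_id = ids, log2fc = lfc, pvalue = p, padj = padj,
             stringsAsFactors = FALSE)
}
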