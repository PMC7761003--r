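#' Scoring scheme for the local-alignment conservation screen
#'
#' Match/mismatch and affine-gap parameters for [smith_waterman()] plus the
#' Karlin-Altschul constants K and lambda used by [alignment_evalue()].  The
#' defaults use BLASTN-like relative weights (+2/-3, gap open -5, extend -2);
#' K and lambda are fixed screening constants for this scheme, not fitted to
#' any reference database, so E-values are comparable within a screen but are
#' not NCBI BLAST statistics.  A validity check requires the expected score
#' of a random aligned base pair to be negative (otherwise local-alignment
#' statistics break down).
#'
#' @param match Positive match reward.
#' @param mismatch,gap_open,gap_extend Negative penalties; a gap of length L
#'   costs `gap_open + L * gap_extend`.
#' @param K,lambda Positive Karlin-Altschul constants.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L,
                           gap_open = -5L, gap_extend = -2L,
                           K = 0.1, lambda = 0.5) {
  if (match <= 0) od_config_error("match reward must be positive")
  if (mismatch >= 0 || gap_open >= 0 || gap_extend >= 0) {
    od_config_error("mismatch and gap penalties must be negative")
  }
  if (K <= 0 || lambda <= 0) od_config_error("K and lambda must be positive")
  # uniform background: a random pair matches with probability 1/4
  if (match / 4 + 3 * mismatch / 4 >= 0) {
    od_config_error("expected score of random pairs must be negative")
  }
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 K = K, lambda = lambda),
            class = "scoring_scheme")
}

check_sequence <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || nchar(x) == 0L) {
    od_domain_error(what, " must be a nonempty sequence")
  }
  x <- toupper(x)
  if (grepl("[^ACGTN]", x)) {
    od_domain_error(what, " contains characters outside {A,C,G,T,N}")
  }
  x
}

#' Optimal local alignment of two nucleotide sequences
#'
#' Smith-Waterman local alignment under affine gap costs (Gotoh recurrences),
#' computed exactly by dynamic programming in C++.  Traceback is fully
#' deterministic: ties are resolved diagonal > up > left, and the reported
#' alignment ends at the first maximum-score cell in row-major order.  `N`
#' scores as a mismatch against everything, including another `N`.
#'
#' @param q,s Query and subject sequences over {A,C,G,T,N} (case
#'   insensitive).
#' @param scheme A [scoring_scheme()].
#' @return List with `score` (raw alignment score), `aln_length` (alignment
#'   columns, gaps included), `identity` (matches / columns),
#'   start/end coordinates in both sequences, and the two aligned strings.
#' @examples
#' smith_waterman("ACGTACGT", "ACGTACGT")$score
#' @export
smith_waterman <- function(q, s, scheme = scoring_scheme()) {
  q <- check_sequence(q, "query")
  s <- check_sequence(s, "subject")
  .sw_align(q, s, scheme$match, scheme$mismatch,
            scheme$gap_open, scheme$gap_extend)
}

#' Karlin-Altschul E-value of an alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least S between a query of length m and a database
#' of total length n under the scheme's constants.
#'
#' @param score Nonnegative raw alignment score.
#' @param query_len,db_len Positive sequence / database lengths.
#' @param scheme A [scoring_scheme()] supplying K and lambda.
#' @return Positive numeric E-value.
#' @export
alignment_evalue <- function(score, query_len, db_len,
                             scheme = scoring_scheme()) {
  if (any(query_len <= 0) || any(db_len <= 0)) {
    od_domain_error("sequence lengths must be positive")
  }
  if (any(score < 0)) od_domain_error("score must be nonnegative")
  scheme$K * query_len * db_len * exp(-scheme$lambda * score)
}

#' Screen query lncRNAs for sequence conservation against a subject set
#'
#' For every query sequence the best local alignment against each subject is
#' computed and scored with a Karlin-Altschul E-value in which the database
#' length is the total subject length.  A query is called conserved when its
#' best hit (smallest E-value; ties broken by higher score, then subject
#' order) satisfies `evalue < e_threshold` and `aln_length > min_length`
#' (strictly, alignment columns including gaps).  The default thresholds —
#' E < 1e-5 and length > 50 — are the usual cross-species lncRNA screening
#' cutoffs.
#'
#' @param query,subjects Named character vectors of sequences, or paths to
#'   FASTA files.
#' @param scheme A [scoring_scheme()].
#' @param e_threshold E-value cutoff.
#' @param min_length Minimum alignment length (exclusive).
#' @return List with `conserved` (character vector of conserved query IDs)
#'   and `results` — a data.frame (query_id, best_subject, score, aln_length,
#'   identity, evalue, conserved) with one row per query.
#' @export
conservation_screen <- function(query, subjects, scheme = scoring_scheme(),
                                e_threshold = 1e-5, min_length = 50) {
  if (is.character(query) && length(query) == 1L && file.exists(query) &&
      is.null(names(query))) {
    query <- read_fasta(query)
  }
  if (is.character(subjects) && length(subjects) == 1L &&
      file.exists(subjects) && is.null(names(subjects))) {
    subjects <- read_fasta(subjects)
  }
  if (!length(query) || !length(subjects)) {
    od_format_error("query and subject sets must be nonempty")
  }
  if (is.null(names(query))) names(query) <- paste0("query", seq_along(query))
  if (is.null(names(subjects))) {
    names(subjects) <- paste0("subject", seq_along(subjects))
  }
  db_len <- sum(nchar(subjects))

  rows <- lapply(names(query), function(qid) {
    q <- query[[qid]]
    best <- NULL
    for (sid in names(subjects)) {
      aln <- smith_waterman(q, subjects[[sid]], scheme)
      ev <- alignment_evalue(aln$score, nchar(q), db_len, scheme)
      cand <- list(subject = sid, score = aln$score,
                   aln_length = aln$aln_length, identity = aln$identity,
                   evalue = ev)
      if (is.null(best) || ev < best$evalue ||
          (ev == best$evalue && cand$score > best$score)) {
        best <- cand
      }
    }
    data.frame(query_id = qid, best_subject = best$subject,
               score = best$score, aln_length = best$aln_length,
               identity = best$identity, evalue = best$evalue,
               conserved = best$evalue < e_threshold &&
                 best$aln_length > min_length,
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(conserved = results$query_id[results$conserved], results = results)
}
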