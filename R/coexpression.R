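#' Build a lncRNA-to-coding-gene correlation network
#'
#' Computes the Pearson correlation across samples between every lncRNA row
#' and every coding-gene row of an expression matrix and keeps the edges
#' passing both cutoffs: squared correlation above `r2_threshold` and
#' (unadjusted) p-value below `p_threshold`.  The default cutoffs, r^2 > 0.9
#' and p < 0.001, retain only near-deterministic co-expression partners.
#' P-values come from the t transform `t = r * sqrt((n-2)/(1-r^2))` on n - 2
#' degrees of freedom and are deliberately not multiplicity-adjusted: the
#' screen is a fixed raw-p cutoff, not an FDR procedure.
#'
#' Rows with zero variance have undefined correlations; they are excluded
#' from pairing with a warning.  The returned edge list is ordered by
#' (lnc_id, coding_id) in the order the IDs were supplied, independent of any
#' internal blocking.
#'
#' @param m Numeric expression matrix, genes x samples (>= 4 samples).
#' @param lnc_ids,coding_ids Disjoint sets of row names of `m`.
#' @param r2_threshold Squared-correlation cutoff, in (0, 1).
#' @param p_threshold P-value cutoff, in (0, 1).
#' @return data.frame(lnc_id, coding_id, r, pvalue), one row per retained
#'   edge.
#' @examples
#' sim <- simulate_coexpression(n_lnc = 2, n_coding = 20, n_samples = 30,
#'                              module_size = 5, seed = 3)
#' nrow(correlation_network(sim$matrix, sim$lnc_ids, sim$coding_ids))
#' @export
correlation_network <- function(m, lnc_ids, coding_ids,
                                r2_threshold = 0.9, p_threshold = 0.001) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  if (ncol(m) < 4L) od_domain_error("need >= 4 samples for the network")
  if (length(intersect(lnc_ids, coding_ids))) {
    od_config_error("lnc_ids and coding_ids must be disjoint")
  }
  missing <- setdiff(c(lnc_ids, coding_ids), rownames(m))
  if (length(missing)) {
    od_config_error("IDs absent from the matrix: ",
                    paste(head(missing, 5), collapse = ", "))
  }
  if (!(r2_threshold > 0 && r2_threshold < 1) ||
      !(p_threshold > 0 && p_threshold < 1)) {
    od_config_error("thresholds must lie in (0, 1)")
  }

  rv <- apply(m[c(lnc_ids, coding_ids), , drop = FALSE], 1, var)
  flat <- names(rv)[rv == 0]
  if (length(flat)) {
    warning(sprintf("%d zero-variance row(s) excluded from the network",
                    length(flat)))
    lnc_ids <- setdiff(lnc_ids, flat)
    coding_ids <- setdiff(coding_ids, flat)
  }
  if (!length(lnc_ids) || !length(coding_ids)) {
    return(data.frame(lnc_id = character(), coding_id = character(),
                      r = numeric(), pvalue = numeric(),
                      stringsAsFactors = FALSE))
  }

  n <- ncol(m)
  r <- cor(t(m[lnc_ids, , drop = FALSE]), t(m[coding_ids, , drop = FALSE]))
  # guard against |r| marginally above 1 from floating-point roundoff
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pval <- 2 * pt(-abs(tstat), n - 2)
  pval[r^2 >= 1] <- 0

  keep <- which(r^2 > r2_threshold & pval < p_threshold, arr.ind = TRUE)
  out <- data.frame(
    lnc_id = lnc_ids[keep[, 1L]],
    coding_id = coding_ids[keep[, 2L]],
    r = r[keep],
    pvalue = pval[keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(match(out$lnc_id, lnc_ids),
                   match(out$coding_id, coding_ids)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collect per-lncRNA partner sets from an edge list
#'
#' @param edges Edge list as from [correlation_network()].
#' @return Named list mapping lnc_id to the character vector of its
#'   correlated coding genes.
#' @export
partner_sets <- function(edges) {
  split(edges$coding_id, edges$lnc_id)
}

#' Maximum cross-species partner-set overlap per lncRNA
#'
#' Functional conservation proxy for lncRNAs: each human lncRNA's correlated
#' coding-gene set is compared against every mouse lncRNA's set after mapping
#' mouse genes into human symbol space through the ortholog map (unmapped
#' genes are dropped), and the best overlap percentage is reported.  A human
#' lncRNA whose comparison universe is empty (no mouse partner maps to a
#' human symbol) scores 0 with a warning.
#'
#' Denominators: `human_set` divides the intersection by the human lncRNA's
#' set size; `min_set` by the smaller of the two sets; `jaccard` by the union.
#'
#' @param human,mouse Named lists of partner sets (see [partner_sets()]);
#'   human sets hold human symbols, mouse sets mouse symbols.
#' @param orthologs One-to-one data.frame(human_symbol, mouse_symbol).
#' @param denominator Overlap normalization; `human_set` by default.
#' @return Named numeric vector (per human lncRNA) of maximum overlap
#'   percentages in [0, 100].
#' @export
max_overlap_percentage <- function(human, mouse, orthologs,
                                   denominator = c("human_set", "min_set",
                                                   "jaccard")) {
  denominator <- match.arg(denominator)
  if (!length(human) || !length(mouse)) {
    od_domain_error("both species need nonempty partner sets")
  }
  if (is.null(orthologs) || nrow(orthologs) == 0L) {
    od_config_error("empty ortholog map")
  }
  to_human <- orthologs$human_symbol
  names(to_human) <- orthologs$mouse_symbol
  mouse_mapped <- lapply(mouse, function(s) {
    unique(unname(to_human[intersect(s, names(to_human))]))
  })
  vapply(names(human), function(lnc) {
    hs <- unique(human[[lnc]])
    best <- 0
    any_universe <- FALSE
    for (ms in mouse_mapped) {
      if (!length(ms)) next
      any_universe <- TRUE
      k <- length(intersect(hs, ms))
      den <- switch(denominator,
        human_set = length(hs),
        min_set = min(length(hs), length(ms)),
        jaccard = length(union(hs, ms))
      )
      if (den > 0) best <- max(best, 100 * k / den)
    }
    if (!any_universe) {
      warning(sprintf("human lncRNA %s: empty mapped comparison universe", lnc))
    }
    best
  }, numeric(1))
}

#' Fraction of lncRNAs whose best overlap stays below a threshold
#'
#' @param pcts Named numeric vector of maximum overlap percentages.
#' @param threshold Percentage threshold.
#' @return Percentage (two decimals) of lncRNAs with max overlap strictly
#'   below `threshold`.
#' @export
overlap_distribution_summary <- function(pcts, threshold) {
  if (!length(pcts)) od_domain_error("empty overlap percentage map")
  round(100 * mean(pcts < threshold), 2)
}
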