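#' Benjamini-Hochberg adjustment with domain checks
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]), with an
#' explicit domain check so out-of-range inputs fail loudly instead of
#' propagating.  Output preserves input order and lies in [0, 1].
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) od_domain_error("empty p-value vector")
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    od_domain_error("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Two-group differential expression on log2 counts
#'
#' A deliberately simple two-group test used to drive the divergence analysis
#' on synthetic data: per gene, the effect is the difference of group means of
#' `log2(count + pseudocount)` (case minus control), the p-value comes from
#' Welch's two-sample t-test on the same transformed values, and `padj` is
#' the Benjamini-Hochberg adjustment across all genes.  It makes no claim to
#' the efficiency of a count-model fit (negative-binomial GLMs, dispersion
#' shrinkage); the downstream divergence classification only consumes
#' (log2fc, pvalue, padj) and is agnostic to the upstream test.
#'
#' A gene with zero variance in both groups gets p = 1 when the group means
#' are equal and p = 0 when they differ (the t statistic degenerates).
#'
#' @param counts Nonnegative matrix, genes x samples, with row names.
#' @param groups Factor or character vector (one entry per column) with
#'   exactly two levels; the first level is the control group, the second the
#'   case, so `log2fc > 0` means higher in case.  At least two samples per
#'   group are required.
#' @param pseudocount Positive offset added before the log transform.
#' @return data.frame(gene_id, log2fc, pvalue, padj), one row per gene.
#' @examples
#' m <- rbind(g1 = c(4, 4, 4, 8, 8, 8), g2 = c(5, 6, 4, 5, 6, 4))
#' differential_expression(m, rep(c("control", "case"), each = 3))
#' @export
differential_expression <- function(counts, groups, pseudocount = 1) {
  if (!is.matrix(counts) || is.null(rownames(counts))) {
    od_domain_error("counts must be a matrix with gene IDs as row names")
  }
  if (anyNA(counts)) od_domain_error("counts contain missing values")
  if (pseudocount <= 0) od_domain_error("pseudocount must be positive")
  if (length(groups) != ncol(counts)) {
    od_domain_error("groups length must equal the number of samples")
  }
  groups <- if (is.factor(groups)) droplevels(groups) else
    factor(groups, levels = unique(groups))
  if (nlevels(groups) != 2L) od_domain_error("exactly two groups are required")
  if (any(table(groups) < 2L)) od_domain_error("need >= 2 samples per group")

  x <- log2(counts + pseudocount)
  a <- x[, groups == levels(groups)[1L], drop = FALSE] # control
  b <- x[, groups == levels(groups)[2L], drop = FALSE] # case
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)

  lfc <- mb - ma
  se2 <- va / na + vb / nb
  tstat <- lfc / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  pvalue <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  pvalue[degenerate] <- ifelse(lfc[degenerate] == 0, 1, 0)

  data.frame(gene_id = rownames(counts), log2fc = lfc, pvalue = pvalue,
             padj = bh_adjust(pvalue), row.names = NULL,
             stringsAsFactors = FALSE)
}
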