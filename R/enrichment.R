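#' Hypergeometric (one-sided Fisher) gene-set overlap test
#'
#' Over-representation test of the overlap between two gene sets drawn from a
#' common universe: the p-value is the hypergeometric upper tail
#' `P(X >= overlap)` with X the overlap of random sets of the same sizes, and
#' the odds ratio is the sample odds ratio of the 2x2 membership table
#' (infinite when a zero off-diagonal cell forces it).  The one-sided
#' enrichment tail is used because module-overlap questions ask whether two
#' sets share more genes than chance, not fewer.
#'
#' @param set_a,set_b Character vectors of gene IDs, both subsets of
#'   `universe`.
#' @param universe Character vector: the gene universe.  Always explicit —
#'   overlap significance is meaningless without stating what could have been
#'   drawn.
#' @return An object of class `overlap_test`: list with set sizes, overlap,
#'   universe size, `odds_ratio`, and `pvalue`.
#' @examples
#' u <- paste0("g", 1:50)
#' fisher_overlap(u[1:10], u[6:15], u)
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  if (!length(universe)) od_domain_error("empty universe")
  universe <- unique(universe)
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  out_a <- setdiff(set_a, universe)
  out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b)) {
    od_domain_error("set members outside the universe: ",
                    paste(head(c(out_a, out_b), 5), collapse = ", "))
  }
  N <- length(universe)
  a <- length(set_a)
  b <- length(set_b)
  k <- length(intersect(set_a, set_b))
  # upper tail P(X >= k) for X ~ Hypergeometric(N, a, b)
  p <- phyper(k - 1, a, N - a, b, lower.tail = FALSE)
  t11 <- k
  t12 <- a - k
  t21 <- b - k
  t22 <- N - a - b + k
  odds <- if (t12 * t21 == 0) {
    if (t11 * t22 == 0) NaN else Inf
  } else {
    (t11 * t22) / (t12 * t21)
  }
  structure(list(set_a_size = a, set_b_size = b, overlap = k,
                 universe_size = N, odds_ratio = odds, pvalue = p),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "Overlap test: %d / (%d x %d) in universe %d; OR = %.3g, p = %.3g\n",
    x$overlap, x$set_a_size, x$set_b_size, x$universe_size,
    x$odds_ratio, x$pvalue))
  invisible(x)
}

#' All-pairs module overlap significance
#'
#' Tests every module of list A against every module of list B with
#' [fisher_overlap()] and adjusts the full matrix of p-values with
#' Benjamini-Hochberg (controlling FDR over all reported cells, not per
#' row).  Cells with adjusted p below `alpha` are flagged significant.
#'
#' @param modules_a,modules_b Named lists of gene-ID vectors, all within
#'   `universe`.
#' @param universe Character vector of the gene universe.
#' @param alpha Significance level for the adjusted p-values.
#' @return List of matrices (`pvalue`, `padj`, `overlap`, `odds_ratio`,
#'   `significant`), rows = modules_a, columns = modules_b.
#' @export
pairwise_module_overlap <- function(modules_a, modules_b, universe,
                                    alpha = 0.05) {
  if (!length(modules_a) || !length(modules_b)) {
    od_config_error("module lists must be nonempty")
  }
  if (is.null(names(modules_a))) {
    names(modules_a) <- paste0("A", seq_along(modules_a))
  }
  if (is.null(names(modules_b))) {
    names(modules_b) <- paste0("B", seq_along(modules_b))
  }
  dims <- list(names(modules_a), names(modules_b))
  shape <- function() matrix(NA_real_, length(modules_a), length(modules_b),
                             dimnames = dims)
  pvalue <- shape(); overlap <- shape(); odds <- shape()
  for (i in seq_along(modules_a)) {
    for (j in seq_along(modules_b)) {
      ft <- fisher_overlap(modules_a[[i]], modules_b[[j]], universe)
      pvalue[i, j] <- ft$pvalue
      overlap[i, j] <- ft$overlap
      odds[i, j] <- ft$odds_ratio
    }
  }
  padj <- matrix(p.adjust(as.vector(pvalue), method = "BH"),
                 nrow = nrow(pvalue), dimnames = dims)
  list(pvalue = pvalue, padj = padj, overlap = overlap, odds_ratio = odds,
       significant = padj < alpha)
}

#' Map a mouse gene set into human symbol space
#'
#' Cross-species set intersections are performed in human symbol space after
#' ortholog mapping; genes without a retained one-to-one ortholog are
#' dropped.
#'
#' @param genes Character vector of mouse symbols.
#' @param orthologs One-to-one data.frame(human_symbol, mouse_symbol).
#' @return Character vector of human symbols.
#' @export
map_to_human <- function(genes, orthologs) {
  to_human <- orthologs$human_symbol
  names(to_human) <- orthologs$mouse_symbol
  unique(unname(to_human[intersect(genes, names(to_human))]))
}
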