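#' Significance criterion for calling a gene regulated
#'
#' A criterion is the rule that decides, per species, whether a gene counts
#' as differentially expressed: which p-value field is thresholded, at what
#' level, and an optional absolute log2 fold-change floor.  Three presets
#' cover the thresholds commonly switched between in cross-species liver
#' comparisons:
#'
#' * `observational` — `padj < 0.05` (FDR-controlled DEG call);
#' * `strict` — `padj < 0.05` and `|log2fc| > 0.4` (signature genes);
#' * `nominal` — `pvalue < 0.05` (unadjusted, for low-powered contrasts).
#'
#' @param preset One of "observational", "strict", "nominal", or NULL to set
#'   the fields directly.
#' @param field "padj" or "pvalue".
#' @param alpha Significance level, in (0, 1).
#' @param min_abs_log2fc Nonnegative fold-change floor (log2 units).
#' @return An object of class `significance_criterion`.
#' @examples
#' significance_criterion("strict")
#' significance_criterion(field = "pvalue", alpha = 0.01)
#' @export
significance_criterion <- function(preset = NULL,
                                   field = c("padj", "pvalue"),
                                   alpha = 0.05,
                                   min_abs_log2fc = 0) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("observational", "strict", "nominal"))
    return(switch(preset,
      observational = significance_criterion(field = "padj", alpha = 0.05),
      strict = significance_criterion(field = "padj", alpha = 0.05,
                                      min_abs_log2fc = 0.4),
      nominal = significance_criterion(field = "pvalue", alpha = 0.05)
    ))
  }
  field <- match.arg(field)
  if (!(alpha > 0 && alpha < 1)) od_config_error("alpha must lie in (0, 1)")
  if (min_abs_log2fc < 0) od_config_error("min_abs_log2fc must be >= 0")
  structure(list(field = field, alpha = alpha,
                 min_abs_log2fc = min_abs_log2fc),
            class = "significance_criterion")
}

#' @export
print.significance_criterion <- function(x, ...) {
  floor_txt <- if (x$min_abs_log2fc > 0) {
    sprintf(" and |log2FC| > %g", x$min_abs_log2fc)
  } else ""
  cat(sprintf("Significance criterion: %s < %g%s\n",
              x$field, x$alpha, floor_txt))
  invisible(x)
}

# Does each record pass the criterion?  NA p-values (e.g. DESeq2 filtered
# padj) and absent records count as not significant.
is_significant <- function(log2fc, p, crit) {
  ok <- !is.na(p) & p < crit$alpha
  if (crit$min_abs_log2fc > 0) {
    ok <- ok & !is.na(log2fc) & abs(log2fc) > crit$min_abs_log2fc
  }
  ok & !is.na(log2fc)
}

divergence_levels <- c("consistent", "opposite", "inconsistent",
                       "not_regulated")

#' Classify ortholog pairs by cross-species regulation agreement
#'
#' For each ortholog pair the classification is driven by the sign product of
#' the two log2 fold changes among genes significant in both species:
#' `consistent` if `log2fc_human * log2fc_mouse > 0`, `opposite` if the
#' product is negative; a gene significant in exactly one species is
#' `inconsistent`, and in neither `not_regulated`.  A significant gene with a
#' fold change of exactly zero makes the sign product ill-defined; such pairs
#' are classed `inconsistent` with a warning rather than silently inflating
#' the consistent or opposite count.
#'
#' @param human_lfc,mouse_lfc Numeric log2 fold changes (NA when the gene is
#'   absent from that species' table).
#' @param human_sig,mouse_sig Logical: does the gene pass the significance
#'   criterion in that species?
#' @return Factor with levels consistent, opposite, inconsistent,
#'   not_regulated.
#' @export
classify_divergence <- function(human_lfc, mouse_lfc, human_sig, mouse_sig) {
  n <- length(human_lfc)
  stopifnot(length(mouse_lfc) == n, length(human_sig) == n,
            length(mouse_sig) == n)
  out <- rep("not_regulated", n)
  one <- xor(human_sig, mouse_sig)
  out[one] <- "inconsistent"
  both <- human_sig & mouse_sig
  prod <- human_lfc * mouse_lfc
  out[both & prod > 0] <- "consistent"
  out[both & prod < 0] <- "opposite"
  zero <- both & prod == 0
  if (any(zero)) {
    warning(sprintf(
      "%d pair(s) significant in both species with a zero log2FC classed as inconsistent",
      sum(zero)))
    out[zero] <- "inconsistent"
  }
  factor(out, levels = divergence_levels)
}

#' Fold-change divergence score
#'
#' The absolute difference of the two species' log2 fold changes,
#' `|log2FC(human) - log2FC(mouse)|` — 0 for identical regulation and, for
#' oppositely signed pairs, the sum of the two magnitudes.
#'
#' @param human_lfc,mouse_lfc Finite numeric log2 fold changes.
#' @return Nonnegative numeric vector.
#' @export
divergence_score <- function(human_lfc, mouse_lfc) {
  if (any(!is.finite(human_lfc)) || any(!is.finite(mouse_lfc))) {
    od_domain_error("divergence_score requires finite log2 fold changes")
  }
  abs(human_lfc - mouse_lfc)
}

#' Fit the cross-species divergence classification for two DEG tables
#'
#' The central estimator of the package.  Two species' differential-expression
#' tables are joined through a one-to-one ortholog map; each ortholog pair is
#' classified as consistent, opposite, inconsistent, or not regulated (see
#' [classify_divergence()]) under a configurable significance criterion, and
#' commonly regulated pairs (consistent or opposite) receive the divergence
#' score `|log2FC(human) - log2FC(mouse)|`.  Genes absent from one species'
#' table are treated as not significant there.
#'
#' @param human,mouse data.frames with columns gene_id, log2fc, pvalue, padj
#'   (as returned by [read_deg_table()] or [differential_expression()]).
#' @param orthologs data.frame(human_symbol, mouse_symbol), one-to-one, as
#'   from [read_ortholog_map()].
#' @param criterion A [significance_criterion()]; the `observational` preset
#'   (padj < 0.05) by default.
#' @return An object of class `ortholog_divergence`: a list with `table`
#'   (one row per ortholog pair: symbols, per-species log2fc/pvalue/padj,
#'   `class`, `score`), `criterion`, and `n_pairs`.  Methods: `print`,
#'   `summary`, `plot`; see also [fold_change_correlation()] and
#'   [score_divergence_comparison()].
#' @examples
#' sim <- simulate_deg_pair(n_genes = 200, n_samples_per_group = 5, seed = 7)
#' dh <- differential_expression(sim$human, sim$groups)
#' dm <- differential_expression(sim$mouse, sim$groups)
#' fit <- ortholog_divergence(dh, dm, sim$ortholog_map)
#' summary(fit)
#' @export
ortholog_divergence <- function(human, mouse, orthologs,
                                criterion = significance_criterion("observational")) {
  for (nm in c("gene_id", "log2fc", "pvalue", "padj")) {
    if (!nm %in% names(human) || !nm %in% names(mouse)) {
      od_format_error("DEG tables need column ", nm)
    }
  }
  if (!all(c("human_symbol", "mouse_symbol") %in% names(orthologs))) {
    od_format_error("ortholog map needs human_symbol and mouse_symbol columns")
  }
  if (!inherits(criterion, "significance_criterion")) {
    od_config_error("criterion must be a significance_criterion")
  }
  if (anyDuplicated(orthologs$human_symbol) ||
      anyDuplicated(orthologs$mouse_symbol)) {
    od_config_error("ortholog map must be one-to-one; apply a policy first")
  }

  hi <- match(orthologs$human_symbol, human$gene_id)
  mi <- match(orthologs$mouse_symbol, mouse$gene_id)
  keep <- !(is.na(hi) & is.na(mi)) # pair absent from both tables: drop
  tab <- data.frame(
    human_symbol = orthologs$human_symbol[keep],
    mouse_symbol = orthologs$mouse_symbol[keep],
    human_log2fc = human$log2fc[hi[keep]],
    human_pvalue = human$pvalue[hi[keep]],
    human_padj = human$padj[hi[keep]],
    mouse_log2fc = mouse$log2fc[mi[keep]],
    mouse_pvalue = mouse$pvalue[mi[keep]],
    mouse_padj = mouse$padj[mi[keep]],
    stringsAsFactors = FALSE
  )
  pfield <- function(side) tab[[paste0(side, "_", criterion$field)]]
  h_sig <- is_significant(tab$human_log2fc, pfield("human"), criterion)
  m_sig <- is_significant(tab$mouse_log2fc, pfield("mouse"), criterion)
  tab$class <- classify_divergence(tab$human_log2fc, tab$mouse_log2fc,
                                   h_sig, m_sig)
  tab$score <- NA_real_
  common <- tab$class %in% c("consistent", "opposite")
  tab$score[common] <- divergence_score(tab$human_log2fc[common],
                                        tab$mouse_log2fc[common])
  structure(list(table = tab, criterion = criterion, n_pairs = nrow(tab)),
            class = "ortholog_divergence")
}

#' @export
print.ortholog_divergence <- function(x, ...) {
  cat("Cross-species ortholog divergence classification\n")
  cat(sprintf("  %d ortholog pairs\n", x$n_pairs))
  print(x$criterion)
  tb <- table(x$table$class)
  cat(sprintf("  consistent %d, opposite %d, inconsistent %d, not regulated %d\n",
              tb[["consistent"]], tb[["opposite"]], tb[["inconsistent"]],
              tb[["not_regulated"]]))
  invisible(x)
}

# Percentages are reported to two decimals with round-half-even, matching
# the convention of the printed summaries this reproduces.
pct2 <- function(num, den) if (den == 0) 0 else round(100 * num / den, 2)

#' Divergence summary from class counts alone
#'
#' Builds the accounting summary directly from the three class counts — the
#' same arithmetic [summary.ortholog_divergence()] applies to a fitted
#' object.  Useful for recomputing published percentages from printed counts:
#' commonly regulated = consistent + opposite; regulated in either species =
#' commonly regulated + inconsistent; class percentages use the
#' regulated-in-either total as denominator, and `pct_opposite_of_common`
#' reports the opposite share among commonly regulated genes.
#'
#' @param consistent,opposite,inconsistent Nonnegative integer counts.
#' @param not_regulated Count of pairs regulated in neither species.
#' @return An object of class `divergence_summary` with the counts, derived
#'   totals, and two-decimal percentages.
#' @examples
#' divergence_summary_from_counts(641, 883, 5525)
#' @export
divergence_summary_from_counts <- function(consistent, opposite, inconsistent,
                                           not_regulated = 0) {
  counts <- c(consistent = consistent, opposite = opposite,
              inconsistent = inconsistent, not_regulated = not_regulated)
  if (any(counts < 0)) od_domain_error("class counts must be nonnegative")
  commonly <- consistent + opposite
  either <- commonly + inconsistent
  structure(list(
    counts = counts,
    commonly_regulated = commonly,
    regulated_in_either = either,
    pct_consistent = pct2(consistent, either),
    pct_opposite = pct2(opposite, either),
    pct_inconsistent = pct2(inconsistent, either),
    pct_opposite_of_common = pct2(opposite, commonly)
  ), class = "divergence_summary")
}

#' Summarize a fitted divergence classification
#'
#' @param object An `ortholog_divergence` fit.
#' @param ... Unused.
#' @return A `divergence_summary`; see [divergence_summary_from_counts()] for
#'   the identities and percentage conventions.
#' @method summary ortholog_divergence
#' @export
summary.ortholog_divergence <- function(object, ...) {
  tb <- table(object$table$class)
  divergence_summary_from_counts(
    consistent = tb[["consistent"]],
    opposite = tb[["opposite"]],
    inconsistent = tb[["inconsistent"]],
    not_regulated = tb[["not_regulated"]]
  )
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat("Divergence summary\n")
  cat(sprintf("  consistent    %6d (%.2f%%)\n", x$counts[["consistent"]],
              x$pct_consistent))
  cat(sprintf("  opposite      %6d (%.2f%%)\n", x$counts[["opposite"]],
              x$pct_opposite))
  cat(sprintf("  inconsistent  %6d (%.2f%%)\n", x$counts[["inconsistent"]],
              x$pct_inconsistent))
  cat(sprintf("  commonly regulated   %6d (opposite share %.2f%%)\n",
              x$commonly_regulated, x$pct_opposite_of_common))
  cat(sprintf("  regulated in either  %6d\n", x$regulated_in_either))
  if (x$counts[["not_regulated"]] > 0) {
    cat(sprintf("  not regulated        %6d\n", x$counts[["not_regulated"]]))
  }
  invisible(x)
}

#' Fold-change scatter of an ortholog divergence fit
#'
#' Plots mouse against human log2 fold changes for every regulated pair,
#' colored by divergence class.
#'
#' @param x An `ortholog_divergence` fit.
#' @param ... Passed to [graphics::plot()].
#' @method plot ortholog_divergence
#' @export
plot.ortholog_divergence <- function(x, ...) {
  tab <- x$table[x$table$class != "not_regulated", , drop = FALSE]
  cols <- c(consistent = "#2166ac", opposite = "#b2182b",
            inconsistent = "grey60", not_regulated = "grey90")
  plot(tab$human_log2fc, tab$mouse_log2fc,
       col = cols[as.character(tab$class)], pch = 16, cex = 0.6,
       xlab = "log2FC (human)", ylab = "log2FC (mouse)", ...)
  abline(h = 0, v = 0, col = "grey80")
  legend("topleft", legend = c("consistent", "opposite", "inconsistent"),
         col = cols[1:3], pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}

#' Pearson correlation of the two species' fold changes
#'
#' Product-moment correlation of (human log2FC, mouse log2FC) over either the
#' commonly regulated pairs only or all pairs regulated in either species,
#' with the p-value from the usual t transform on n - 2 degrees of freedom.
#'
#' @param object An `ortholog_divergence` fit.
#' @param scope "commonly_regulated" (consistent + opposite) or
#'   "regulated_in_either" (also inconsistent).
#' @return List with `r`, `pvalue`, `n`.
#' @export
fold_change_correlation <- function(object,
                                    scope = c("commonly_regulated",
                                              "regulated_in_either")) {
  scope <- match.arg(scope)
  classes <- if (scope == "commonly_regulated") {
    c("consistent", "opposite")
  } else {
    c("consistent", "opposite", "inconsistent")
  }
  tab <- object$table[object$table$class %in% classes, , drop = FALSE]
  tab <- tab[is.finite(tab$human_log2fc) & is.finite(tab$mouse_log2fc), ,
             drop = FALSE]
  if (nrow(tab) < 3L) od_domain_error("need >= 3 pairs in scope")
  if (var(tab$human_log2fc) == 0 || var(tab$mouse_log2fc) == 0) {
    od_domain_error("fold-change correlation undefined: zero variance")
  }
  ct <- cor.test(tab$human_log2fc, tab$mouse_log2fc, method = "pearson")
  list(r = unname(ct$estimate), pvalue = ct$p.value, n = nrow(tab))
}

#' Compare divergence scores of consistent vs opposite pairs
#'
#' Opposite pairs diverge more than consistent pairs by construction
#' (|a| + |b| vs ||a| - |b||); this quantifies the gap with group means,
#' standard errors of the mean, and a two-tailed Welch t-test.
#'
#' @param object An `ortholog_divergence` fit with at least two pairs in each
#'   class.
#' @return List with `consistent_mean`, `consistent_sem`, `opposite_mean`,
#'   `opposite_sem`, `pvalue`, and the group sizes.
#' @export
score_divergence_comparison <- function(object) {
  sc <- function(cl) object$table$score[object$table$class == cl]
  cons <- sc("consistent")
  opp <- sc("opposite")
  if (length(cons) < 2L || length(opp) < 2L) {
    od_domain_error("need >= 2 consistent and >= 2 opposite pairs")
  }
  sem <- function(v) sqrt(var(v) / length(v))
  pv <- if (var(cons) == 0 && var(opp) == 0) {
    if (mean(cons) == mean(opp)) 1 else 0
  } else {
    t.test(cons, opp)$p.value
  }
  list(consistent_mean = mean(cons), consistent_sem = sem(cons),
       opposite_mean = mean(opp), opposite_sem = sem(opp),
       pvalue = pv, n_consistent = length(cons), n_opposite = length(opp))
}
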