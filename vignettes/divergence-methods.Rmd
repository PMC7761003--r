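---
title: "Methods: cross-species divergence classification and its companions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species divergence classification and its companions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthodiv)
```

## The divergence classifier

`ortholog_divergence()` answers one question: given the same contrast run in
human and in mouse, how do orthologous genes move relative to each other?
Each one-to-one ortholog pair is assigned exactly one label from the sign
product of its two log2 fold changes among genes that pass a significance
criterion in both species — `consistent` when the product is positive,
`opposite` when negative — while genes passing in exactly one species are
`inconsistent` and the rest `not_regulated`. Commonly regulated pairs
(consistent or opposite) carry the divergence score
$|\mathrm{logFC}_h - \mathrm{logFC}_m|$, measured in log2 units.

The classifier assumes nothing about how the per-species tables were
produced beyond the (log2fc, pvalue, padj) triple: DESeq2 output, limma
output, or the package's own Welch-t stand-in are interchangeable inputs.
The assumptions that matter are (i) the ortholog map is one-to-one — a
many-to-many relation makes the sign product ill-defined, which is why
`read_ortholog_map()` forces a policy before any classification; and (ii)
fold changes in the two species are on the same (log2) scale.

Two algebraic identities hold on every fit and are asserted by the test
suite: commonly regulated = consistent + opposite, and regulated in either =
commonly regulated + inconsistent. Percentages are reported over the
regulated-in-either denominator, to two decimals with round-half-even; the
summary additionally exposes the opposite share of commonly regulated genes
because published comparisons quote both conventions.

### Significance criterion

The criterion is a single configurable object applied identically to both
species, with three presets:

| preset | rule | typical use |
|---|---|---|
| `observational` | padj < 0.05 | broad DEG calls |
| `strict` | padj < 0.05 and \|log2FC\| > 0.4 | signature genes |
| `nominal` | pvalue < 0.05 | low-powered contrasts |

Published cross-species comparisons switch between these thresholds from
analysis to analysis; making the criterion explicit prevents a silent
mismatch between the two species. A gene absent from one species' table, or
carrying an NA p-value (e.g. an independent-filtering NA from DESeq2),
counts as not significant there rather than erroring. A significant gene
with a fold change of exactly zero is classed `inconsistent` with a warning:
the sign product defines only strict inequalities, and such a pathological
row must not inflate the consistent or opposite count.

`fold_change_correlation()` offers both plausible scopes — commonly
regulated pairs only, or everything regulated in either species — because
either could underlie a published concordance scatter; neither is asserted
as canonical. The p-value uses the standard t transform on $n-2$ degrees of
freedom.

## The differential-expression stand-in

`differential_expression()` is a deliberately transparent two-group test:
effect = difference of group means of $\log_2(\mathrm{count} + 1)$ (case
minus control), p from Welch's t on the same values, padj by
Benjamini–Hochberg. It is *not* a count-model fit — no dispersion shrinkage,
no size-factor normalization — because the divergence layer consumes only
the result triple, and a self-contained, well-understood test keeps the
synthetic pipeline free of heavy model dependencies. The pseudocount
defaults to 1 (conventional; avoids log 0). Degenerate genes with zero
variance in both groups get p = 1 when means agree and p = 0 otherwise.

## What the synthetic generators emulate

All generators draw from named RNG streams derived from one user seed, so
adding or reordering generator calls never perturbs another generator's
draws, and every output is bit-reproducible.

`simulate_deg_pair()` plants a regulation class per ortholog gene
(largest-remainder apportionment, so class counts are deterministic and sum
exactly to n) and produces negative-binomial counts whose case/control mean
ratio equals $2^{\mathrm{lfc}}$, split symmetrically across the two groups.
Defaults, fixed once as a realistic bulk RNA-seq contrast: class proportions
0.10/0.10/0.10/0.10/0.60 (a strong intervention regulates a few tens of
percent of genes; inconsistent genes planted as regulated in one species and
flat in the other); |log2FC| lognormal with median 1.5 and sdlog 0.3
(clearly detectable effects, spread but bounded away from the 0.4 floor);
dispersion 0.1 (typical for within-strain liver RNA-seq); baseline means
lognormal with median 300 and sdlog 0.8 (moderately expressed genes). What
it does **not** emulate: library-size differences, batch effects,
correlation between genes, low-count genes near the detection limit, or
DESeq2-specific behaviour — so passing recovery tests show the
classification arithmetic is right, not that any particular DE tool is
reproduced on real data.

`simulate_coexpression()` plants disjoint lncRNA modules whose members load
on a shared latent factor ($x = \rho z + \sigma \varepsilon$, member–member
population correlation $\rho^2/(\rho^2+\sigma^2)$); membership is a random
disjoint draw from the coding pool so two simulated species plant different
modules and the cross-species overlap distribution is non-degenerate.
`simulate_sequence_pairs()` creates conserved pairs as per-base-substituted
copies and non-conserved pairs as independent uniform sequences — a
homogeneous substitution process with no indels, splice isoforms, or repeat
structure. `simulate_chimeric_counts()` emulates quantification against a
concatenated two-species reference with `human_`/`mouse_` ID prefixes.

## Co-expression networks and functional overlap

`correlation_network()` keeps lncRNA–coding edges with squared Pearson
correlation above 0.9 **and** raw p below 0.001. The "|R²| > 0.9" screening
convention is read as squared correlation (the absolute-value bars are
redundant since r² is nonnegative). P-values are intentionally not
multiplicity-adjusted — the screen is a fixed raw-p cutoff. Zero-variance
rows are excluded with a warning (their correlation is undefined), and the
edge list ordering is deterministic in the supplied ID order.

`max_overlap_percentage()` maps each mouse lncRNA's partner set into human
symbol space through the ortholog map (unmapped partners dropped) and
reports, per human lncRNA, the best overlap percentage across mouse lncRNAs.
The default denominator is the human lncRNA's own set size (`human_set`);
`min_set` and `jaccard` remain selectable because the published statistic
does not pin the denominator down, and the direction (per-human vs
per-mouse) is the caller's choice of which sets to pass as `human`.

## The conservation screen

`smith_waterman()` computes the optimal local alignment under affine gaps
(a gap of length $L$ costs `gap_open` $+ L\,\cdot$ `gap_extend`), with a
fully deterministic traceback: operation priority diagonal > up > left,
gap-open preferred over gap-extend inside a gap state, and the alignment
ending at the first maximum-score cell in row-major order. `N` scores as a
mismatch against everything, including another `N`. The implementation is
exact dynamic programming, verified in the test suite against an exhaustive
path-enumeration oracle on short sequences and against an independent
reference aligner on longer ones.

E-values take the Karlin–Altschul form $E = K m n e^{-\lambda S}$ with
defaults +2/−3/−5/−2 and $K = 0.1$, $\lambda = 0.5$. These are screening
constants for this scoring scheme, not NCBI BLAST statistics: the screen's
validity surface is recovery of planted conserved pairs, not BLAST parity.
A query is conserved when its best hit (smallest E; ties to the higher
score, then subject order) has $E < 10^{-5}$ and alignment length strictly
greater than 50 columns, gap columns included — the strict inequality
follows the conventional "length > 50" phrasing. Only the single best local
alignment per pair is considered; suboptimal-HSP enumeration is out of
scope for a thresholded screen. The screen runs query→subject; swap the
arguments for the other direction.

## Overlap significance

`fisher_overlap()` is the one-sided enrichment tail: module-overlap
questions ask whether two sets share *more* genes than chance. The p-value
is the exact hypergeometric upper tail; the odds ratio is the sample odds
ratio of the 2×2 table (infinite on a forcing zero cell). The universe is a
required explicit argument, never defaulted, because overlap significance is
meaningless without stating the sampling frame.
`pairwise_module_overlap()` adjusts the full matrix of p-values by
Benjamini–Hochberg, controlling FDR over all reported cells rather than per
row. Cross-species intersections are taken in human symbol space after
ortholog mapping (`map_to_human()`), reusing the same one-to-one policies as
the classifier.

## Pipeline and reproducibility

`run_full_pipeline()` materializes every stage's output (count matrices,
DEG tables, divergence table, edge lists, conservation table, JSON report)
plus a manifest of file MD5s, the full configuration and the seed; identical
config and seed give a byte-identical bundle, and the structured log records
per-stage in/out counts so the accounting identities are auditable from the
log alone. Stages are always materialized rather than piped in memory so
any stage can be replaced by real data — supplying `human_deg`, `mouse_deg`
and `orthologs` paths in the config swaps the simulated contrast for
external DEG tables. Configuration is validated before any compute.

## Problem sizes and numerical conventions

The validation suite runs the classifier recovery at 2000 genes with 20
samples per group, the network recovery at 5 modules × 10 partners over 50
samples, and the conservation recovery at 20 pairs of 300-base sequences —
sizes at which every planted signal is comfortably estimable while a full
run completes in seconds. Reported percentages round half-even to two
decimals. Duplicate gene IDs in a DEG table keep the smallest-p row (with a
warning); symbols are whitespace-trimmed but never case-folded, since
human/mouse symbol case conventions (ABC1 vs Abc1) must be resolved through
the ortholog map, not string matching.

## Known limitations

The DE stand-in is less powerful than a count-model fit at small n and low
counts; recovery bounds were chosen for the synthetic regime above.
E-values are scheme-specific and not comparable to BLAST reports. The
classifier treats "absent from the table" and "tested but not significant"
identically, which is the conservative reading but conflates filtered and
unmeasured genes. Nothing in the package corrects for the double-dipping
inherent in classifying on the same data used to call significance; the
divergence percentages describe the supplied tables, not population
parameters.
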