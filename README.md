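# orthodiv

Cross-species transcriptome divergence analysis for ortholog pairs.

## The problem

Mouse is the default model for human liver physiology, yet matched
transcriptome contrasts (disease vs. control, agonist vs. vehicle, knockdown
vs. scramble) routinely regulate thousands of genes differently in the two
species — including many orthologs pushed in *opposite* directions. Deciding
how much of a mouse result transfers to human requires an explicit
accounting of that divergence. `orthodiv` provides the estimator for that
accounting plus the surrounding tooling: a species-prefix splitter for
chimeric (humanized-mouse) count tables, lncRNA–coding co-expression
networks, a sequence-conservation screen for lncRNAs, gene-set overlap
tests, and a synthetic-data generator with known ground truth so every step
is verifiable.

## The model

Given per-species differential-expression results joined through a
one-to-one human–mouse ortholog map, each ortholog pair with log2 fold
changes (logFC<sub>h</sub>, logFC<sub>m</sub>) is classified under a
significance criterion (padj < 0.05 by default):

* **consistent** — significant in both species and
  logFC<sub>h</sub> × logFC<sub>m</sub> > 0;
* **opposite** — significant in both and
  logFC<sub>h</sub> × logFC<sub>m</sub> < 0;
* **inconsistent** — significant in exactly one species;
* **not regulated** — significant in neither.

Commonly regulated pairs receive the divergence score
|logFC<sub>h</sub> − logFC<sub>m</sub>|, and the summary reports the class
counts, the additive identities (commonly regulated = consistent + opposite;
regulated in either = commonly regulated + inconsistent) and two-decimal
percentages over the regulated-in-either denominator. Fold-change
concordance is measured with Pearson correlation; consistent-vs-opposite
score gaps with a two-tailed Welch t-test.

Supporting statistics: lncRNA–coding edges pass |r|² > 0.9 and p < 0.001
(Pearson, t-transform p, unadjusted); lncRNA sequence conservation uses an
exact Smith–Waterman local aligner (affine gaps, Gotoh recurrences, in C++)
with Karlin–Altschul E-values `E = K·m·n·e^(−λS)`, thresholded at E < 10⁻⁵
and alignment length > 50; gene-set overlap significance is the
hypergeometric upper tail.

## Worked example

```r
library(orthodiv)

# a synthetic two-species contrast with known ground truth:
# 10% consistent, 10% opposite, 20% inconsistent, 60% null genes
sim   <- simulate_deg_pair(n_genes = 1000, n_samples_per_group = 10, seed = 42)
deg_h <- differential_expression(sim$human, sim$groups)
deg_m <- differential_expression(sim$mouse, sim$groups)

fit <- ortholog_divergence(deg_h, deg_m, sim$ortholog_map,
                           significance_criterion("strict"))
summary(fit)
#> Divergence summary
#>   consistent       100 (24.57%)
#>   opposite          99 (24.32%)
#>   inconsistent     208 (51.11%)
#>   commonly regulated      199 (opposite share 49.75%)
#>   regulated in either     407
#>   not regulated           593
```

The planted 10/10/20 percent classes are recovered as 100/99/208 of 1000
genes. Opposite pairs diverge far more than consistent ones:

```r
cmp <- score_divergence_comparison(fit)
#> mean divergence score: consistent 0.64, opposite 3.32 (p = 5.3e-62)
```

The same arithmetic applied to printed counts from a published human
NAFLD vs. mouse HFD comparison (641 consistent, 883 opposite, 5525
inconsistent orthologs):

```r
divergence_summary_from_counts(641, 883, 5525)
#> Divergence summary
#>   consistent       641 (9.09%)
#>   opposite         883 (12.53%)
#>   inconsistent    5525 (78.38%)
#>   commonly regulated     1524 (opposite share 57.94%)
#>   regulated in either    7049
```

i.e. 12.53% of regulated orthologs are oppositely regulated and 78.38%
inconsistently. `run_full_pipeline(default_run_config(seed = 1))`
orchestrates the whole synthetic study (simulate → DE → divergence →
networks → conservation) into a materialized, manifest-stamped bundle.

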