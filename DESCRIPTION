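Package: orthodiv
Title: Cross-Species Transcriptome Divergence Analysis for Ortholog Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how differently two species regulate the same genes.
    Ortholog pairs of differential-expression results are classified as
    consistently, oppositely, or inconsistently regulated from the sign
    product of their log2 fold changes; a fold-change divergence score
    (|log2FC difference|) and Pearson concordance summarize each contrast.
    Companion tools build lncRNA-to-coding-gene co-expression networks with
    correlation thresholds, screen lncRNA sequence conservation with a
    Smith-Waterman local aligner and Karlin-Altschul E-values, test gene-set
    overlap significance with the hypergeometric tail, split chimeric
    (humanized-mouse) count tables by species prefix, and simulate all
    required inputs with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
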