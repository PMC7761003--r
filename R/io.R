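#' Default column-name dialect for DEG tables
#'
#' The default names follow DESeq2 result tables (`gene_id`,
#' `log2FoldChange`, `pvalue`, `padj`); pass a modified copy to
#' [read_deg_table()] for other dialects.
#'
#' @return Named character vector mapping canonical field names
#'   (gene_id, log2fc, pvalue, padj) to file column names.
#' @export
deg_columns <- function() {
  c(gene_id = "gene_id", log2fc = "log2FoldChange",
    pvalue = "pvalue", padj = "padj")
}

#' Read a differential-expression result table
#'
#' Reads a tab-separated DEG table into the canonical four-column layout
#' (`gene_id`, `log2fc`, `pvalue`, `padj`).  Symbols are whitespace-trimmed
#' but never case-folded: human/mouse symbol case conventions are resolved
#' only through an ortholog map.  Rows whose numeric fields do not parse are
#' rejected with row-numbered errors; duplicated gene IDs keep the row with
#' the smallest p-value (a warning reports how many were dropped).
#'
#' @param path Path to a TSV file with a header.
#' @param species_tag Optional label stored in the `species` attribute.
#' @param columns Column-name dialect, as from [deg_columns()].
#' @return data.frame with columns gene_id, log2fc, pvalue, padj.
#' @export
read_deg_table <- function(path, species_tag = NULL, columns = deg_columns()) {
  stopifnot(all(c("gene_id", "log2fc", "pvalue", "padj") %in% names(columns)))
  if (!file.exists(path)) od_format_error("file not found: ", path)
  raw <- tryCatch(
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
               colClasses = "character"),
    error = function(e) od_format_error("cannot read ", path, ": ",
                                        conditionMessage(e))
  )
  if (nrow(raw) == 0L) od_format_error("empty DEG table: ", path)
  missing <- setdiff(unname(columns), names(raw))
  if (length(missing)) {
    od_format_error("DEG table ", path, " lacks required column(s): ",
                    paste(missing, collapse = ", "))
  }
  out <- data.frame(
    gene_id = trimws(raw[[columns[["gene_id"]]]]),
    log2fc = raw[[columns[["log2fc"]]]],
    pvalue = raw[[columns[["pvalue"]]]],
    padj = raw[[columns[["padj"]]]],
    stringsAsFactors = FALSE
  )
  for (field in c("log2fc", "pvalue", "padj")) {
    parsed <- suppressWarnings(as.numeric(out[[field]]))
    bad <- which(is.na(parsed) & !is.na(out[[field]]) &
                   trimws(out[[field]]) != "NA")
    if (length(bad)) {
      od_format_error("unparseable ", field, " in ", path, " at data row(s) ",
                      paste(head(bad, 5), collapse = ", "))
    }
    out[[field]] <- parsed
  }
  if (any(out$gene_id == "")) {
    od_format_error("empty gene_id in ", path, " at data row(s) ",
                    paste(head(which(out$gene_id == ""), 5), collapse = ", "))
  }
  if (anyDuplicated(out$gene_id)) {
    n0 <- nrow(out)
    out <- out[order(out$gene_id, out$pvalue), , drop = FALSE]
    out <- out[!duplicated(out$gene_id), , drop = FALSE]
    # restore first-appearance order
    out <- out[order(match(out$gene_id, trimws(raw[[columns[["gene_id"]]]]))), ,
               drop = FALSE]
    warning(sprintf("%d duplicate gene_id row(s) dropped (kept smallest p)",
                    n0 - nrow(out)))
  }
  rownames(out) <- NULL
  if (!is.null(species_tag)) attr(out, "species") <- species_tag
  out
}

#' Write a DEG table in the default dialect
#'
#' @param deg data.frame with gene_id, log2fc, pvalue, padj.
#' @param path Output TSV path.
#' @param columns Column-name dialect for the header.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(deg, path, columns = deg_columns()) {
  out <- deg[, c("gene_id", "log2fc", "pvalue", "padj")]
  names(out) <- unname(columns[c("gene_id", "log2fc", "pvalue", "padj")])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a human/mouse ortholog map
#'
#' Reads a two-column TSV of (human_symbol, mouse_symbol) pairs, MGI-homology
#' style.  Under the default `strict_one_to_one` policy every symbol that
#' participates in a one-to-many or many-to-many relation is dropped (the
#' count of dropped pairs is reported in the `dropped` attribute and a
#' warning); `first_wins` keeps the first file-order occurrence of each
#' symbol instead.  A header line is detected by non-symbol-like content
#' ("human"/"mouse"/"symbol", case-insensitive) in the first row.
#'
#' @param path Path to a two-column TSV.
#' @param policy Either "strict_one_to_one" or "first_wins".
#' @return data.frame(human_symbol, mouse_symbol), one-to-one after
#'   canonicalization, with attribute `dropped` (pairs removed by policy).
#' @export
read_ortholog_map <- function(path,
                              policy = c("strict_one_to_one", "first_wins")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) od_format_error("file not found: ", path)
  raw <- tryCatch(
    read.delim(path, header = FALSE, stringsAsFactors = FALSE,
               colClasses = "character"),
    error = function(e) od_format_error("cannot read ", path, ": ",
                                        conditionMessage(e))
  )
  if (ncol(raw) < 2L) od_format_error("ortholog map needs two columns: ", path)
  if (nrow(raw) >= 1L &&
      any(grepl("human|mouse|symbol", unlist(raw[1, 1:2]), ignore.case = TRUE))) {
    raw <- raw[-1, , drop = FALSE]
  }
  pairs <- data.frame(human_symbol = trimws(raw[[1]]),
                      mouse_symbol = trimws(raw[[2]]),
                      stringsAsFactors = FALSE)
  pairs <- pairs[pairs$human_symbol != "" & pairs$mouse_symbol != "", ,
                 drop = FALSE]
  pairs <- pairs[!duplicated(pairs), , drop = FALSE] # exact duplicates are harmless
  n0 <- nrow(pairs)
  if (policy == "strict_one_to_one") {
    keep <- !(pairs$human_symbol %in%
                pairs$human_symbol[duplicated(pairs$human_symbol)]) &
      !(pairs$mouse_symbol %in%
          pairs$mouse_symbol[duplicated(pairs$mouse_symbol)])
    pairs <- pairs[keep, , drop = FALSE]
  } else {
    pairs <- pairs[!duplicated(pairs$human_symbol), , drop = FALSE]
    pairs <- pairs[!duplicated(pairs$mouse_symbol), , drop = FALSE]
  }
  dropped <- n0 - nrow(pairs)
  if (nrow(pairs) == 0L) {
    od_format_error("no ortholog pairs retained from ", path,
                    " under policy ", policy)
  }
  if (dropped > 0) {
    warning(sprintf("ortholog map: %d pair(s) dropped by %s policy",
                    dropped, policy))
  }
  rownames(pairs) <- NULL
  attr(pairs, "dropped") <- dropped
  pairs
}

#' Read / write a gene-by-sample count matrix
#'
#' TSV layout: first column `gene_id`, remaining columns one per sample.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene IDs as row names.
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) od_format_error("file not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(raw) < 2L) od_format_error("count matrix needs samples: ", path)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- trimws(as.character(raw[[1]]))
  m
}

#' @rdname read_count_matrix
#' @param m Matrix with row names.
#' @export
write_count_matrix <- function(m, path) {
  out <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split a chimeric count table by species prefix
#'
#' Rows of a combined human+mouse quantification carry a `human_` or `mouse_`
#' gene-ID prefix (from alignment to a concatenated two-species reference).
#' The split strips the prefix and partitions the rows exactly; any row
#' without a recognized prefix is a format error.
#'
#' @param counts Matrix whose row names carry the species prefix.
#' @return List with `human` and `mouse` matrices (prefixes stripped).
#' @seealso [prefix_chimeric()] for the inverse.
#' @export
split_chimeric <- function(counts) {
  ids <- rownames(counts)
  if (is.null(ids)) od_format_error("chimeric table has no gene IDs")
  is_h <- startsWith(ids, "human_")
  is_m <- startsWith(ids, "mouse_")
  bad <- ids[!(is_h | is_m)]
  if (length(bad)) {
    od_format_error("gene ID(s) without a human_/mouse_ prefix: ",
                    paste(head(bad, 5), collapse = ", "))
  }
  human <- counts[is_h, , drop = FALSE]
  mouse <- counts[is_m, , drop = FALSE]
  rownames(human) <- substring(rownames(human), nchar("human_") + 1L)
  rownames(mouse) <- substring(rownames(mouse), nchar("mouse_") + 1L)
  if (nrow(human) == 0L) warning("chimeric split: empty human partition")
  if (nrow(mouse) == 0L) warning("chimeric split: empty mouse partition")
  list(human = human, mouse = mouse)
}

#' Recombine species matrices into a chimeric table
#'
#' @param human,mouse Count matrices with unprefixed gene IDs and identical
#'   sample columns.
#' @return Combined matrix with `human_`/`mouse_` prefixed row names.
#' @export
prefix_chimeric <- function(human, mouse) {
  stopifnot(ncol(human) == ncol(mouse))
  out <- rbind(human, mouse)
  rownames(out) <- c(paste0("human_", rownames(human)),
                     paste0("mouse_", rownames(mouse)))
  out
}

#' Read / write nucleotide FASTA as a named character vector
#'
#' Thin wrappers over Biostrings for the plain multi-record FASTA files the
#' conservation screen consumes.
#'
#' @param path FASTA path.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) od_format_error("file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) od_format_error(
                    "cannot read FASTA ", path, ": ", conditionMessage(e)))
  if (length(set) == 0L) od_format_error("empty FASTA: ", path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set)) # first token of the defline
  out
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
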