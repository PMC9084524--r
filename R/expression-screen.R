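#' Read a grouped TPM expression matrix
#'
#' Dialect: tab-separated; first line `#group<TAB>label...` assigns each
#' sample column to a tissue group, second line the header
#' `gene<TAB>sample...`, then one row per gene with TPM values.
#'
#' @param path path to the TSV.
#' @return list with `tpm` (gene x sample numeric matrix) and `groups`
#'   (named character vector sample -> group).
#' @export
readExpressionMatrix <- function(path) {
  lines <- readLines(path, n = 2L)
  if (!grepl("^#group\t", lines[1L]))
    stop("expected a '#group' header line")
  groups <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L]
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          check.names = FALSE)
  tpm <- as.matrix(df[, -1L, drop = FALSE])
  rownames(tpm) <- df[[1L]]
  if (length(groups) != ncol(tpm))
    stop("group header length does not match sample count")
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  list(tpm = tpm, groups = stats::setNames(groups, colnames(tpm)))
}

#' Write a grouped TPM expression matrix
#'
#' @param tpm gene x sample matrix.
#' @param groups named character vector sample -> group.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(tpm, groups, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#group", unname(groups[colnames(tpm)])),
                   collapse = "\t"), con)
  writeLines(paste(c("gene", colnames(tpm)), collapse = "\t"), con)
  utils::write.table(data.frame(gene = rownames(tpm), tpm,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

.groupMeans <- function(tpm, groups) {
  gs <- unique(unname(groups))
  out <- vapply(gs, function(g)
    rowMeans(tpm[, names(groups)[groups == g], drop = FALSE]),
    numeric(nrow(tpm)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L,
                                       dimnames = list(rownames(tpm), gs))
  out
}

#' Tissue-enrichment scores for a target group
#'
#' Two-step averaging: per gene, first the mean TPM of each tissue group,
#' then `log2fc = log2((target mean + eps) / (mean of the other group
#' means + eps))`. Genes whose target-group mean TPM does not exceed
#' `minTpm` are excluded (lowly expressed genes cannot be meaningfully
#' ranked for enrichment).
#'
#' @param tpm gene x sample non-negative matrix.
#' @param groups named character vector sample -> group; every sample
#'   column must be mapped.
#' @param targetGroup group to score enrichment for (e.g. `"placenta"`).
#' @param minTpm expression floor on the target-group mean (default 10).
#' @param pseudocount epsilon guarding zero denominators (default 0.01
#'   TPM).
#' @return data.frame `gene`, `target_mean_tpm`, `log2fc`, sorted by
#'   decreasing `log2fc`.
#' @export
enrichmentScores <- function(tpm, groups, targetGroup, minTpm = 10,
                             pseudocount = 0.01) {
  missing <- setdiff(colnames(tpm), names(groups))
  if (length(missing))
    stop("ungrouped sample(s): ", paste(missing, collapse = ", "))
  gm <- .groupMeans(tpm, groups)
  if (!targetGroup %in% colnames(gm))
    stop("target group '", targetGroup, "' not present")
  if (ncol(gm) < 2L) stop("need at least two groups")
  target <- gm[, targetGroup]
  others <- rowMeans(gm[, setdiff(colnames(gm), targetGroup), drop = FALSE])
  lfc <- log2((target + pseudocount) / (others + pseudocount))
  out <- data.frame(gene = rownames(tpm), target_mean_tpm = unname(target),
                    log2fc = unname(lfc))
  out <- out[out$target_mean_tpm > minTpm, , drop = FALSE]
  out <- out[order(-out$log2fc, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enrichment of one group against a set of reference groups
#'
#' `log2((mean of group A + eps) / (mean of the listed groups' means +
#' eps))` per gene, e.g. trophoblast-stem cells versus the average of
#' embryonic and extraembryonic-endoderm stem cells.
#'
#' @param tpm gene x sample matrix.
#' @param groups named character vector sample -> group.
#' @param groupA numerator group.
#' @param groupBSet character vector of reference groups.
#' @param pseudocount epsilon (default 0.01 TPM).
#' @return data.frame `gene`, `mean_a`, `mean_b`, `log2fc`.
#' @export
pairwiseEnrichment <- function(tpm, groups, groupA, groupBSet,
                               pseudocount = 0.01) {
  gm <- .groupMeans(tpm, groups)
  absent <- setdiff(c(groupA, groupBSet), colnames(gm))
  if (length(absent))
    stop("group(s) not present: ", paste(absent, collapse = ", "))
  a <- gm[, groupA]
  b <- rowMeans(gm[, groupBSet, drop = FALSE])
  data.frame(gene = rownames(tpm), mean_a = unname(a), mean_b = unname(b),
             log2fc = unname(log2((a + pseudocount) / (b + pseudocount))))
}

#' Genes differentially expressed in specific comparisons only
#'
#' Selects genes significant (adjusted p below `padjThreshold`) in every
#' comparison of `required` and not significant in every comparison of
#' `absent`. The default reproduces the "single-paralog-specific" rule:
#' differentially expressed in the single-KO and double-KO comparisons
#' but not in the paralog's KO. Missing or `NA` adjusted p-values count
#' as not significant.
#'
#' @param de data.frame with columns `gene`, `comparison`, `log2fc`,
#'   `padj`.
#' @param padjThreshold significance threshold (default 0.05).
#' @param required comparisons that must be significant.
#' @param absent comparisons that must not be.
#' @return character vector of gene ids.
#' @export
specificDEGenes <- function(de, padjThreshold = 0.05,
                            required = c("M3KO", "DKO"), absent = "M2KO") {
  need <- c("gene", "comparison", "padj")
  if (!all(need %in% names(de)))
    stop("de must have columns: ", paste(need, collapse = ", "))
  if (nrow(de) == 0L) return(character(0))
  missing <- setdiff(c(required, absent), unique(de$comparison))
  if (length(missing))
    stop("comparison(s) absent from table: ", paste(missing, collapse = ", "))
  genes <- unique(de$gene)
  sig <- function(g, comp) {
    p <- de$padj[de$gene == g & de$comparison == comp]
    length(p) == 1L && !is.na(p) && p < padjThreshold
  }
  keep <- vapply(genes, function(g)
    all(vapply(required, function(cc) sig(g, cc), logical(1L))) &&
    !any(vapply(absent, function(cc) sig(g, cc), logical(1L))), logical(1L))
  genes[keep]
}

#' Candidate gene sets under relaxed differential-expression cutoffs
#'
#' For an under-powered comparison, selects genes with raw `pvalue <
#' pThreshold` and `|log2fc| > minAbsLog2fc` (both strict), split by the
#' sign of the fold change.
#'
#' @param de data.frame for a single comparison with columns `gene`,
#'   `pvalue`, `log2fc`.
#' @param pThreshold raw p-value cutoff (default 0.1).
#' @param minAbsLog2fc absolute log2 fold-change cutoff (default 0.1).
#' @return list with character vectors `up` and `down`.
#' @export
relaxedCandidateGenes <- function(de, pThreshold = 0.1, minAbsLog2fc = 0.1) {
  need <- c("gene", "pvalue", "log2fc")
  if (!all(need %in% names(de)))
    stop("de must have columns: ", paste(need, collapse = ", "))
  sel <- !is.na(de$pvalue) & de$pvalue < pThreshold &
    abs(de$log2fc) > minAbsLog2fc
  list(up = de$gene[sel & de$log2fc > 0],
       down = de$gene[sel & de$log2fc < 0])
}
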