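#' @import methods
NULL

RNA_BASES <- c("A", "C", "G", "U")

DONOR_CLASSES <- c("ancestral_long", "ancestral_short_skip",
                   "eutherian_specific", "lineage_specific")

COVERAGE_LEVELS <- c("N", "VLOW", "LOW", "OK", "SOK")

#' 7-mer Z-score table
#'
#' Container for RNAcompete-style one-sided Z-scores, one per RNA 7-mer.
#' The Z-score is a unitless proxy for the relative affinity of an
#' RNA-binding protein for that 7-mer; higher means stronger preferred
#' binding. Kmers are stored in the RNA alphabet (A, C, G, U).
#'
#' @slot proteinId single string naming the assayed protein (may be empty).
#' @slot zscore named numeric vector; names are unique 7-mers over
#'   \{A,C,G,U\}, values are finite Z-scores.
#'
#' @seealso [readKmerTable()], [topKmers()], [motifContribution()]
#' @export
setClass("KmerZscoreTable",
  representation(proteinId = "character", zscore = "numeric"))

setValidity("KmerZscoreTable", function(object) {
  z <- object@zscore
  k <- names(z)
  if (length(object@proteinId) != 1L)
    return("proteinId must be a single string")
  if (length(z) > 0L) {
    if (is.null(k) || anyNA(k))
      return("zscore must be named by kmer")
    if (anyDuplicated(k))
      return("kmers must be unique")
    if (any(nchar(k) != 7L))
      return("kmers must have length exactly 7")
    if (any(grepl("[^ACGU]", k)))
      return("kmers must be over the RNA alphabet {A,C,G,U}")
    if (anyNA(z) || any(!is.finite(z)))
      return("zscores must be finite and non-missing")
  }
  TRUE
})

#' Construct a KmerZscoreTable
#'
#' @param zscore named numeric vector of Z-scores; names are 7-mers. A DNA
#'   alphabet (T instead of U) is converted to RNA.
#' @param proteinId optional protein identifier.
#' @return a [KmerZscoreTable-class] object.
#' @examples
#' tab <- KmerZscoreTable(c(GCUUGCA = 12.3, AAAAAAA = 0.1))
#' maxZscore(tab)
#' @export
KmerZscoreTable <- function(zscore, proteinId = "") {
  names(zscore) <- toupper(chartr("Tt", "Uu", names(zscore)))
  new("KmerZscoreTable", proteinId = proteinId, zscore = zscore)
}

setMethod("show", "KmerZscoreTable", function(object) {
  cat("KmerZscoreTable", if (nzchar(object@proteinId))
    paste0("[", object@proteinId, "]") else "",
    "with", length(object@zscore), "7-mers\n")
  if (length(object@zscore) > 0L) {
    top <- utils::head(sort(object@zscore, decreasing = TRUE), 3L)
    cat("  top:", paste(names(top), signif(top, 4), collapse = ", "), "\n")
  }
})

#' @describeIn KmerZscoreTable number of 7-mers in the table.
#' @param x a KmerZscoreTable.
#' @export
setMethod("length", "KmerZscoreTable", function(x) length(x@zscore))

#' Result of a within-litter rank permutation test
#'
#' @slot observed observed test statistic (sum over litters of the KO
#'   rank-sum, with weights ranked ascending within each litter).
#' @slot nIter number of permutations evaluated (Monte Carlo draws, or the
#'   number of distinct within-litter labelings under exact enumeration).
#' @slot nAsExtreme number of permutations at least as extreme as observed
#'   in the tested direction.
#' @slot p p-value; `nAsExtreme / nIter` by default, or the smoothed
#'   `(nAsExtreme + 1) / (nIter + 1)` variant.
#' @slot seed integer seed used for Monte Carlo sampling (NA when exact).
#' @slot alternative `"ko_heavier"` or `"ko_lighter"`.
#' @slot method `"exact"` or `"montecarlo"`.
#' @slot littersUsed litter ids contributing to the statistic.
#' @slot littersDropped litter ids dropped for lacking both genotypes.
#' @export
setClass("PermutationResult",
  representation(observed = "numeric", nIter = "numeric",
                 nAsExtreme = "numeric", p = "numeric", seed = "integer",
                 alternative = "character", method = "character",
                 littersUsed = "character", littersDropped = "character"))

setValidity("PermutationResult", function(object) {
  if (object@p < 0 || object@p > 1) return("p must be in [0, 1]")
  if (object@nIter < 1) return("nIter must be >= 1")
  if (object@nAsExtreme < 0 || object@nAsExtreme > object@nIter)
    return("nAsExtreme must be in [0, nIter]")
  TRUE
})

setMethod("show", "PermutationResult", function(object) {
  cat("Within-litter rank permutation test (", object@method, ")\n", sep = "")
  cat("  litters:", length(object@littersUsed),
      if (length(object@littersDropped))
        paste0("(", length(object@littersDropped), " dropped)") else "", "\n")
  cat("  alternative:", object@alternative, "\n")
  cat("  observed KO rank-sum:", object@observed, "\n")
  cat("  p = ", object@p, " (", object@nAsExtreme, "/", object@nIter,
      " as extreme)\n", sep = "")
})

#' @describeIn PermutationResult extract the p-value.
#' @param object a PermutationResult.
#' @export
setGeneric("pvalue", function(object) standardGeneric("pvalue"))

#' @rdname PermutationResult
#' @export
setMethod("pvalue", "PermutationResult", function(object) object@p)

#' A proximal/distal polyadenylation-site pair for one gene
#'
#' Holds the two competing cleavage sites of a gene in mRNA orientation
#' (proximal = nearer the stop codon) together with a 2 x n_samples matrix
#' of supporting read counts.
#'
#' @slot geneId gene identifier.
#' @slot chrom chromosome name.
#' @slot strand mRNA strand, "+" or "-".
#' @slot proximalPos 1-based cleavage coordinate of the proximal site.
#' @slot distalPos 1-based cleavage coordinate of the distal site.
#' @slot counts numeric matrix with rows `proximal` and `distal` and one
#'   column per sample; non-negative.
#' @seealso [proximalUsage()], [testPairs()]
#' @export
setClass("PolyAPair",
  representation(geneId = "character", chrom = "character",
                 strand = "character", proximalPos = "numeric",
                 distalPos = "numeric", counts = "matrix"))

setValidity("PolyAPair", function(object) {
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  ok <- if (object@strand == "+") object@proximalPos < object@distalPos
        else object@proximalPos > object@distalPos
  if (!ok) return("proximal site must lie 5' of the distal site in mRNA orientation")
  if (!identical(rownames(object@counts), c("proximal", "distal")))
    return("counts must have rows 'proximal' and 'distal'")
  if (any(object@counts < 0) || anyNA(object@counts))
    return("counts must be non-negative")
  if (is.null(colnames(object@counts)))
    return("counts columns must be named by sample")
  TRUE
})

#' Construct a PolyAPair
#'
#' @param geneId gene identifier.
#' @param chrom chromosome name.
#' @param strand mRNA strand ("+" or "-").
#' @param proximalPos,distalPos 1-based cleavage coordinates; the proximal
#'   site must be 5' of the distal one in mRNA orientation.
#' @param counts 2 x n_samples matrix (rows `proximal`, `distal`).
#' @return a [PolyAPair-class] object.
#' @export
PolyAPair <- function(geneId, chrom, strand, proximalPos, distalPos, counts) {
  new("PolyAPair", geneId = geneId, chrom = chrom, strand = strand,
      proximalPos = as.numeric(proximalPos), distalPos = as.numeric(distalPos),
      counts = counts)
}

setMethod("show", "PolyAPair", function(object) {
  cat("PolyAPair", object@geneId, " ", object@chrom,
      ":", object@proximalPos, "/", object@distalPos,
      " (", object@strand, "), ", ncol(object@counts), " samples\n", sep = "")
})
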