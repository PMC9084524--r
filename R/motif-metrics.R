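#' Read a 7-mer Z-score table
#'
#' Parses a two-column tab-separated file of (kmer, zscore), with an
#' optional header line. DNA-alphabet kmers (T) are converted to RNA (U).
#' Rows with a missing Z-score are dropped and their count reported.
#'
#' @param path path to the TSV file.
#' @param proteinId optional protein identifier attached to the table.
#' @return a [KmerZscoreTable-class].
#' @export
readKmerTable <- function(path, proteinId = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  hasHeader <- length(first) == 1L &&
    is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1L]][2L])))
  df <- utils::read.table(path, sep = "\t", header = hasHeader,
                          colClasses = c("character", "character"),
                          col.names = c("kmer", "zscore"))
  z <- suppressWarnings(as.numeric(df$zscore))
  nDropped <- sum(is.na(z))
  if (nDropped > 0L)
    message("dropped ", nDropped, " row(s) with missing Z-score")
  keep <- !is.na(z)
  KmerZscoreTable(stats::setNames(z[keep], df$kmer[keep]), proteinId)
}

#' Write a 7-mer Z-score table
#'
#' @param table a [KmerZscoreTable-class].
#' @param path output path.
#' @param header write a `kmer<TAB>zscore` header line.
#' @return `path`, invisibly.
#' @export
writeKmerTable <- function(table, path, header = TRUE) {
  stopifnot(is(table, "KmerZscoreTable"))
  df <- data.frame(kmer = names(table@zscore), zscore = table@zscore)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

.checkMotifs <- function(motifs) {
  motifs <- toupper(chartr("Tt", "Uu", motifs))
  if (length(motifs) == 0L) stop("motif set must be non-empty")
  if (any(nchar(motifs) > 7L)) stop("motifs must be at most 7 nt long")
  if (any(nchar(motifs) < 1L)) stop("motifs must be non-empty strings")
  if (any(grepl("[^ACGU]", motifs)))
    stop("motifs must be over the RNA alphabet {A,C,G,U}")
  motifs
}

#' Top-ranked 7-mers by Z-score
#'
#' Returns the n highest-scoring 7-mers in descending Z-score order. Ties
#' are broken lexicographically on the kmer so the top-n boundary is
#' deterministic and independent of input order.
#'
#' @param table a [KmerZscoreTable-class].
#' @param n number of kmers to return (capped at the table size).
#' @return data.frame with columns `kmer` and `zscore`.
#' @examples
#' tab <- KmerZscoreTable(c(GCUUAAA = 10, GCAGCAA = 10, AAAAAAA = 1))
#' topKmers(tab, 2)  # GCAGCAA ranks before GCUUAAA on the tie
#' @export
topKmers <- function(table, n) {
  stopifnot(is(table, "KmerZscoreTable"))
  if (length(table) == 0L) stop("empty Z-score table")
  if (n < 1L) stop("n must be >= 1")
  z <- table@zscore
  ord <- order(-z, names(z))
  ord <- ord[seq_len(min(n, length(z)))]
  data.frame(kmer = names(z)[ord], zscore = unname(z[ord]))
}

#' Z-score of the top-ranked 7-mer
#'
#' @param table a [KmerZscoreTable-class].
#' @return the maximum Z-score; a proxy for the strength of the protein's
#'   strongest binding preference.
#' @export
maxZscore <- function(table) {
  stopifnot(is(table, "KmerZscoreTable"))
  if (length(table) == 0L) stop("empty Z-score table")
  max(table@zscore)
}

#' Z-score contribution of a motif set among the top-n 7-mers
#'
#' Sums the Z-scores of the top-n 7-mers that contain at least one of the
#' given motifs as a literal substring and divides by the summed Z of all
#' top-n 7-mers. This is the fraction of the protein's accumulated top-end
#' affinity attributable to the motif set.
#'
#' @param table a [KmerZscoreTable-class].
#' @param motifs character vector of literal motifs (<= 7 nt, RNA or DNA
#'   alphabet), e.g. `"GCUU"`, `"GCAGC"` or `c("GCA","GCC","GCG","GCU")`.
#' @param n number of top kmers considered (default 100).
#' @param percent return the value on a 0-100 scale.
#' @return fraction in \[0, 1\] (or percent).
#' @examples
#' tab <- KmerZscoreTable(c(GCUUAAA = 10, GCAGCAA = 10,
#'                          AAAAAAA = 10, CCCCCCC = 10))
#' motifContribution(tab, "GCUU", n = 4)  # 0.25
#' @export
motifContribution <- function(table, motifs, n = 100L, percent = FALSE) {
  motifs <- .checkMotifs(motifs)
  top <- topKmers(table, n)
  denom <- sum(top$zscore)
  if (denom <= 0)
    stop("total Z-score of the top-", n, " 7-mers is non-positive; ",
         "contribution fraction undefined")
  hit <- Reduce(`|`, lapply(motifs, function(m) grepl(m, top$kmer, fixed = TRUE)))
  val <- sum(top$zscore[hit]) / denom
  if (percent) 100 * val else val
}

# Start positions of "GC" occurrences within one kmer (1-based).
.gcPositions <- function(kmer) {
  p <- gregexpr("GC", kmer, fixed = TRUE)[[1L]]
  p[p > 0L]
}

#' Partition of GC-motif affinity by the base following the GC
#'
#' Among the top-n 7-mers, takes those containing a GC dinucleotide with a
#' following base and classifies each by that base (i.e. GCA vs GCC vs GCG
#' vs GCU), then reports the fraction of summed Z-score in each class.
#' With `singleGC = TRUE` (default) only kmers with exactly one GC
#' occurrence qualify, which makes the classification unambiguous; set it
#' to FALSE to admit multi-GC kmers, whose Z-score then counts once per
#' distinct following base.
#'
#' 7-mers whose only GC occupies the final two positions have no following
#' base and are excluded.
#'
#' @param table a [KmerZscoreTable-class].
#' @param n number of top kmers considered.
#' @param singleGC restrict to kmers with exactly one GC occurrence.
#' @return named numeric vector over A, C, G, U summing to 1.
#' @examples
#' tab <- KmerZscoreTable(c(AGCAAAA = 6, AGCUAAA = 2, AGCUAAC = 2))
#' gcFollowingBasePartition(tab, n = 3)  # A: 0.6, U: 0.4
#' @export
gcFollowingBasePartition <- function(table, n = 100L, singleGC = TRUE) {
  top <- topKmers(table, n)
  sums <- stats::setNames(numeric(4L), RNA_BASES)
  any_qual <- FALSE
  for (i in seq_len(nrow(top))) {
    pos <- .gcPositions(top$kmer[i])
    pos <- pos[pos <= nchar(top$kmer[i]) - 2L]  # need a following base
    if (length(pos) == 0L) next
    if (singleGC && length(pos) != 1L) next
    bases <- unique(substr(rep(top$kmer[i], length(pos)), pos + 2L, pos + 2L))
    sums[bases] <- sums[bases] + top$zscore[i]
    any_qual <- TRUE
  }
  if (!any_qual)
    stop("no qualifying GC-containing 7-mers among the top-", n)
  total <- sum(sums)
  if (total <= 0)
    stop("summed Z-score of qualifying 7-mers is non-positive")
  sums / total
}

#' Log2 ratio of 1-bp- versus 2-bp-spaced GC-pair affinity
#'
#' Among the top-n 7-mers, compares the summed Z-score of kmers matching
#' GCxGC (two GC dinucleotides separated by one arbitrary base) against
#' those matching GCxxGC (two-base spacer):
#' `log2(sum Z over GCxGC / sum Z over GCxxGC)`. Positive values indicate
#' a preference for the shorter spacing.
#'
#' When either class is absent from the top-n or has a non-positive Z sum
#' the ratio is undefined; `NA` is returned with attribute `reason`.
#'
#' @param table a [KmerZscoreTable-class].
#' @param n number of top kmers considered.
#' @return a single numeric (or flagged `NA`).
#' @export
gcSpacingLogRatio <- function(table, n = 100L) {
  top <- topKmers(table, n)
  s1 <- sum(top$zscore[grepl("GC.GC", top$kmer)])
  s2 <- sum(top$zscore[grepl("GC..GC", top$kmer)])
  has1 <- any(grepl("GC.GC", top$kmer))
  has2 <- any(grepl("GC..GC", top$kmer))
  if (!has1 || !has2 || s1 <= 0 || s2 <= 0) {
    reason <- if (!has1) "no GCxGC kmer in top-n"
      else if (!has2) "no GCxxGC kmer in top-n"
      else "non-positive class Z sum"
    return(structure(NA_real_, reason = reason))
  }
  log2(s1 / s2)
}
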