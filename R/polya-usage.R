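#' Read 3'-seq read records
#'
#' Two dialects are accepted. BED6
#' (`chrom start end sample_id score strand`; 0-based half-open, strand is
#' the alignment strand) is converted to 1-based coordinates with the
#' alignment's 5' end at `start + 1` for `+` alignments and at `end` for
#' `-` alignments. The flat TSV dialect is
#' `chrom<TAB>strand<TAB>five_prime_pos<TAB>sample_id` (1-based).
#'
#' @param path path to the file.
#' @param format `"auto"`, `"bed"` or `"tsv"`.
#' @return data.frame with columns `chrom`, `alignment_strand`,
#'   `five_prime_pos`, `sample_id`.
#' @export
readThreePrimeReads <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), alignment_strand = character(),
                      five_prime_pos = integer(), sample_id = character()))
  nf <- length(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]])
  if (format == "auto") format <- if (nf >= 6L) "bed" else "tsv"
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "bed") {
    bad <- which(lengths(fields) < 6L)
    if (length(bad)) stop("malformed BED6 line ", bad[1L])
    chrom <- vapply(fields, `[`, "", 1L)
    start <- as.integer(vapply(fields, `[`, "", 2L))
    end <- as.integer(vapply(fields, `[`, "", 3L))
    sample <- vapply(fields, `[`, "", 4L)
    strand <- vapply(fields, `[`, "", 6L)
    if (any(!strand %in% c("+", "-"))) stop("BED strand must be '+' or '-'")
    pos <- ifelse(strand == "+", start + 1L, end)
  } else {
    bad <- which(lengths(fields) < 4L)
    if (length(bad)) stop("malformed read TSV line ", bad[1L])
    chrom <- vapply(fields, `[`, "", 1L)
    strand <- vapply(fields, `[`, "", 2L)
    if (any(!strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    pos <- as.integer(vapply(fields, `[`, "", 3L))
    sample <- vapply(fields, `[`, "", 4L)
  }
  data.frame(chrom = chrom, alignment_strand = strand,
             five_prime_pos = as.integer(pos), sample_id = sample)
}

#' Write 3'-seq read records
#'
#' @param reads data.frame as returned by [readThreePrimeReads()].
#' @param path output path.
#' @param format `"bed"` (BED6, sample_id in the name column) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeThreePrimeReads <- function(reads, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(
      reads[, c("chrom", "alignment_strand", "five_prime_pos", "sample_id")],
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    start <- ifelse(reads$alignment_strand == "+",
                    reads$five_prime_pos - 1L, reads$five_prime_pos - 1L)
    end <- start + 1L
    bed <- data.frame(reads$chrom, start, end, reads$sample_id, 0L,
                      reads$alignment_strand)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Infer cleavage sites from 3'-seq alignments
#'
#' In reverse-primed 3'-seq the sequencing read runs antisense to the
#' mRNA, so the cleavage/polyadenylation position is the 5' end of the
#' alignment and the mRNA strand is the inverse of the alignment strand.
#'
#' @param reads data.frame with columns `chrom`, `alignment_strand`,
#'   `five_prime_pos`, `sample_id`.
#' @return data.frame with columns `chrom`, `mrna_strand`, `position`,
#'   `sample_id`.
#' @export
inferCleavageSites <- function(reads) {
  data.frame(chrom = reads$chrom,
             mrna_strand = ifelse(reads$alignment_strand == "+", "-", "+"),
             position = reads$five_prime_pos,
             sample_id = reads$sample_id)
}

#' Call polyA sites by greedy peak clustering
#'
#' Per chromosome and mRNA strand, repeatedly takes the position with the
#' highest read support, absorbs all remaining reads within
#' `tolerance` nt on either side into a site located at that peak, and
#' continues until no remaining position has at least `minSupport` reads.
#' Every read is assigned to at most one site, and emitted sites on the
#' same chromosome and strand are pairwise more than `tolerance` apart.
#' Equal-support ties pick the smallest coordinate.
#'
#' @param cleavage data.frame from [inferCleavageSites()].
#' @param tolerance clustering half-window in nt (default 50).
#' @param minSupport minimum per-position read support to seed a site.
#' @return a [GenomicRanges::GRanges] of width-1 sites with metadata
#'   columns `support` (reads absorbed) and `mrna_strand`-matching strand.
#' @export
callSites <- function(cleavage, tolerance = 50L, minSupport = 1L) {
  if (tolerance < 0L) stop("tolerance must be >= 0")
  empty <- GenomicRanges::GRanges()
  S4Vectors::mcols(empty)$support <- integer()
  if (nrow(cleavage) == 0L) return(empty)
  parts <- split(cleavage, paste(cleavage$chrom, cleavage$mrna_strand))
  out <- list()
  for (p in parts) {
    counts <- table(p$position)
    pos <- as.integer(names(counts))
    cnt <- as.integer(counts)
    ord <- order(pos)  # table() orders names as strings
    pos <- pos[ord]; cnt <- cnt[ord]
    sites <- integer(); supp <- integer()
    while (length(pos) > 0L) {
      peak <- which.max(cnt)  # ties: first = smallest position
      if (cnt[peak] < minSupport) break
      inWin <- abs(pos - pos[peak]) <= tolerance
      sites <- c(sites, pos[peak])
      supp <- c(supp, sum(cnt[inWin]))
      pos <- pos[!inWin]; cnt <- cnt[!inWin]
    }
    if (length(sites))
      out[[length(out) + 1L]] <- GenomicRanges::GRanges(
        seqnames = p$chrom[1L],
        ranges = IRanges::IRanges(start = sites, width = 1L),
        strand = p$mrna_strand[1L], support = supp)
  }
  if (length(out) == 0L) return(empty)
  # sites from different synthetic chromosomes share no seqlevels
  res <- suppressWarnings(do.call(c, out))
  GenomicRanges::sort(res)
}

#' Per-sample read counts for called sites
#'
#' Assigns each cleavage record to the nearest called site on its
#' chromosome and strand within `tolerance` nt (ties to the smaller
#' coordinate); unassigned reads are dropped. The assignment is a
#' partition: no read counts towards two sites.
#'
#' @param sites GRanges from [callSites()].
#' @param cleavage data.frame from [inferCleavageSites()].
#' @param tolerance assignment half-window in nt.
#' @return integer matrix, one row per site (named `chrom:pos:strand`),
#'   one column per sample.
#' @export
siteCounts <- function(sites, cleavage, tolerance = 50L) {
  samples <- sort(unique(cleavage$sample_id))
  key <- paste0(GenomicRanges::seqnames(sites), ":",
                GenomicRanges::start(sites), ":",
                GenomicRanges::strand(sites))
  m <- matrix(0L, nrow = length(sites), ncol = length(samples),
              dimnames = list(key, samples))
  sChrom <- as.character(GenomicRanges::seqnames(sites))
  sStrand <- as.character(GenomicRanges::strand(sites))
  sPos <- GenomicRanges::start(sites)
  for (i in seq_len(nrow(cleavage))) {
    cand <- which(sChrom == cleavage$chrom[i] &
                  sStrand == cleavage$mrna_strand[i])
    if (length(cand) == 0L) next
    d <- abs(sPos[cand] - cleavage$position[i])
    j <- cand[order(d, sPos[cand])[1L]]
    if (abs(sPos[j] - cleavage$position[i]) <= tolerance)
      m[j, cleavage$sample_id[i]] <- m[j, cleavage$sample_id[i]] + 1L
  }
  m
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Filter internal-priming artifacts from called polyA sites
#'
#' Oligo-dT priming on genomic A-rich tracts produces spurious 3' ends.
#' A site is kept iff a polyadenylation-signal hexamer (default AATAAA or
#' ATTAAA, mRNA-strand sense) occurs in the upstream window, OR its
#' downstream genomic context is not A-rich. The downstream 20 nt (mRNA
#' sense) is A-rich when it contains a run of at least `aRun` A's or at
#' least `aCount` A's in total. Removed sites are reported in the
#' `removed` attribute with the reason.
#'
#' @param sites GRanges of width-1 sites (strand = mRNA strand).
#' @param genome a [Biostrings::DNAStringSet] covering the sites'
#'   chromosomes.
#' @param signalWindow upstream search window in nt, `c(near, far)`
#'   relative to the cleavage position (default `c(10, 40)`).
#' @param signals polyA-signal hexamers, DNA alphabet, mRNA sense.
#' @param aRun minimum A-run length marking A-rich context (default 6).
#' @param aWindow downstream window length in nt (default 20).
#' @param aCount minimum A count within `aWindow` marking A-rich context
#'   (default 12).
#' @return the retained sites; attribute `removed` is a data.frame of
#'   removed site keys and reasons.
#' @export
filterInternalPriming <- function(sites, genome,
                                  signalWindow = c(10L, 40L),
                                  signals = c("AATAAA", "ATTAAA"),
                                  aRun = 6L, aWindow = 20L, aCount = 12L) {
  if (length(sites) == 0L) {
    attr(sites, "removed") <- data.frame(site = character(),
                                         reason = character())
    return(sites)
  }
  chroms <- as.character(GenomicRanges::seqnames(sites))
  missing <- setdiff(unique(chroms), names(genome))
  if (length(missing))
    stop("genome lacks sequence for: ", paste(missing, collapse = ", "))
  keep <- logical(length(sites))
  reason <- character(length(sites))
  runPat <- paste0("A{", aRun, ",}")
  for (i in seq_along(sites)) {
    chromSeq <- genome[[chroms[i]]]
    len <- length(chromSeq)
    pos <- GenomicRanges::start(sites)[i]
    plus <- as.character(GenomicRanges::strand(sites)[i]) == "+"
    if (pos < 1L || pos > len)
      stop("site outside chromosome bounds: ", chroms[i], ":", pos)
    if (plus) {
      upFrom <- max(1L, pos - signalWindow[2L])
      upTo <- min(len, pos - signalWindow[1L])
      up <- if (upFrom <= upTo)
        as.character(Biostrings::subseq(chromSeq, upFrom, upTo)) else ""
      dnFrom <- min(len, pos + 1L); dnTo <- min(len, pos + aWindow)
      dn <- if (pos < len)
        as.character(Biostrings::subseq(chromSeq, dnFrom, dnTo)) else ""
    } else {
      upFrom <- max(1L, pos + signalWindow[1L])
      upTo <- min(len, pos + signalWindow[2L])
      up <- if (upFrom <= upTo)
        .revcomp(as.character(Biostrings::subseq(chromSeq, upFrom, upTo)))
        else ""
      dnFrom <- max(1L, pos - aWindow); dnTo <- max(1L, pos - 1L)
      dn <- if (pos > 1L)
        .revcomp(as.character(Biostrings::subseq(chromSeq, dnFrom, dnTo)))
        else ""
    }
    hasSignal <- any(vapply(signals, function(s) grepl(s, up, fixed = TRUE),
                            logical(1L)))
    aRich <- grepl(runPat, dn) ||
      nchar(gsub("[^A]", "", dn)) >= aCount
    keep[i] <- hasSignal || !aRich
    if (!keep[i])
      reason[i] <- if (!hasSignal && aRich)
        "A-rich downstream, no upstream polyA signal" else "A-rich downstream"
  }
  removed <- data.frame(
    site = paste0(chroms, ":", GenomicRanges::start(sites), ":",
                  GenomicRanges::strand(sites))[!keep],
    reason = reason[!keep])
  if (nrow(removed) > 0L)
    message("removed ", nrow(removed), " putative internal-priming site(s)")
  out <- sites[keep]
  attr(out, "removed") <- removed
  out
}

#' Percent usage of the proximal polyA site
#'
#' `PU = 100 * proximal / (proximal + distal)` for one sample of a pair.
#'
#' @param pair a [PolyAPair-class].
#' @param sample sample (column) name; all samples if omitted.
#' @return percent in \[0, 100\]; `NA` when the sample has no reads on
#'   either site.
#' @export
proximalUsage <- function(pair, sample = NULL) {
  stopifnot(is(pair, "PolyAPair"))
  cnt <- pair@counts
  if (!is.null(sample)) {
    if (!sample %in% colnames(cnt)) stop("unknown sample: ", sample)
    cnt <- cnt[, sample, drop = FALSE]
  }
  tot <- colSums(cnt)
  out <- ifelse(tot > 0, 100 * cnt["proximal", ] / tot, NA_real_)
  stats::setNames(out, colnames(cnt))
}

#' Build a proximal/distal pair for one gene from called sites
#'
#' Takes the two highest-support sites on the gene's chromosome and
#' orders them proximal/distal in mRNA orientation.
#'
#' @param sites GRanges of retained sites.
#' @param counts site x sample matrix from [siteCounts()].
#' @param geneId gene identifier.
#' @param chrom the gene's chromosome.
#' @return a [PolyAPair-class], or `NULL` when fewer than two sites exist
#'   on the chromosome.
#' @export
buildGenePair <- function(sites, counts, geneId, chrom) {
  sel <- which(as.character(GenomicRanges::seqnames(sites)) == chrom)
  if (length(sel) < 2L) return(NULL)
  sel <- sel[order(-sites$support[sel])][1:2]
  pos <- GenomicRanges::start(sites)[sel]
  strand <- as.character(GenomicRanges::strand(sites)[sel[1L]])
  ord <- if (strand == "+") order(pos) else order(-pos)
  sel <- sel[ord]; pos <- pos[ord]
  key <- paste0(chrom, ":", pos, ":", strand)
  cnt <- counts[key, , drop = FALSE]
  rownames(cnt) <- c("proximal", "distal")
  PolyAPair(geneId, chrom, strand, pos[1L], pos[2L], cnt)
}

#' Test polyA pairs for condition-dependent usage shifts
#'
#' For each pair and each KO-vs-reference comparison, replicate counts
#' are summed into a 2x2 table (proximal/distal x condition) and tested
#' with Fisher's exact test; p-values are Benjamini-Hochberg corrected
#' across all pairs within each comparison. The effect size is the log2
#' fold change of proximal *usage* (proximal fraction in KO over
#' proximal fraction in reference), so equal scaling of both sites
#' leaves it at zero. A pair is `enhanced` (proximal up-regulated in KO)
#' or `repressed` when the two sites' usage changes point in opposite
#' directions and the FDR is below `fdrThreshold`; significant pairs
#' without opposite-direction site changes are labelled `ko_up`/`ko_down`
#' by the sign of the proximal change; everything else is `ns`. Tables
#' with a zero cell (which includes zero margins) get a 0.5 continuity
#' correction for the estimate and are flagged `degenerate`.
#'
#' Precomputed per-pair FDR values can be supplied via `fdrTable`
#' (data.frame `pair_id`, `comparison`, `fdr`) to bypass the built-in
#' test while keeping the labelling rules.
#'
#' @param pairs named list of [PolyAPair-class] objects.
#' @param design named character vector mapping sample to condition.
#' @param ref reference condition label (default `"WT"`).
#' @param fdrThreshold significance threshold (default 0.1).
#' @param fdrTable optional externally computed FDRs (see above).
#' @return data.frame with one row per pair x comparison: `pair_id`,
#'   `gene_id`, `comparison`, `log2fc`, `p`, `fdr`, `status`,
#'   `degenerate`.
#' @export
testPairs <- function(pairs, design, ref = "WT", fdrThreshold = 0.1,
                      fdrTable = NULL) {
  if (length(pairs) == 0L) stop("no pairs to test")
  if (is.null(names(pairs))) names(pairs) <- vapply(pairs, slot, "", "geneId")
  conds <- setdiff(unique(design), ref)
  if (length(conds) == 0L) stop("design has no non-reference condition")
  rows <- list()
  for (cond in conds) {
    for (pid in names(pairs)) {
      pair <- pairs[[pid]]
      cnt <- pair@counts
      missing <- setdiff(colnames(cnt), names(design))
      if (length(missing))
        stop("samples missing from design: ", paste(missing, collapse = ", "))
      koS <- colnames(cnt)[design[colnames(cnt)] == cond]
      wtS <- colnames(cnt)[design[colnames(cnt)] == ref]
      if (length(koS) == 0L || length(wtS) == 0L)
        stop("comparison ", cond, " vs ", ref, " needs samples in both conditions")
      tab <- cbind(ko = rowSums(cnt[, koS, drop = FALSE]),
                   wt = rowSums(cnt[, wtS, drop = FALSE]))
      if (sum(tab) == 0) stop("pair ", pid, " has zero total counts")
      degenerate <- any(tab == 0)  # zero cell or margin
      est <- if (degenerate) tab + 0.5 else tab
      fko <- est["proximal", "ko"] / sum(est[, "ko"])
      fwt <- est["proximal", "wt"] / sum(est[, "wt"])
      log2fc <- log2(fko / fwt)
      dko <- est["distal", "ko"] / sum(est[, "ko"])
      dwt <- est["distal", "wt"] / sum(est[, "wt"])
      distalLfc <- log2(dko / dwt)
      p <- stats::fisher.test(round(tab))$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = pid, gene_id = pair@geneId, comparison = cond,
        log2fc = log2fc, distal_log2fc = distalLfc, p = p,
        degenerate = degenerate)
    }
  }
  res <- do.call(rbind, rows)
  res$fdr <- NA_real_
  for (cond in conds) {
    sel <- res$comparison == cond
    res$fdr[sel] <- stats::p.adjust(res$p[sel], method = "BH")
  }
  if (!is.null(fdrTable)) {
    m <- match(paste(res$pair_id, res$comparison),
               paste(fdrTable$pair_id, fdrTable$comparison))
    res$fdr[!is.na(m)] <- fdrTable$fdr[m[!is.na(m)]]
  }
  opposite <- sign(res$log2fc) * sign(res$distal_log2fc) < 0
  sig <- res$fdr < fdrThreshold
  res$status <- "ns"
  res$status[sig & opposite & res$log2fc > 0] <- "enhanced"
  res$status[sig & opposite & res$log2fc < 0] <- "repressed"
  res$status[sig & !opposite & res$log2fc > 0] <- "ko_up"
  res$status[sig & !opposite & res$log2fc < 0] <- "ko_down"
  res
}

#' Select one representative polyA pair per gene
#'
#' Ranked selection among each gene's pairs. The candidate set is the
#' pairs significant in the maximal number of KO-vs-reference
#' comparisons. Then: (i) take the candidate with the largest absolute
#' log2 fold change if its total reads are at least
#' `readFrac1` x the reads of the gene's highest-read pair; (ii) else
#' fall back to the highest-read pair among all pairs (disable with
#' `maxReadFallback = FALSE`); (iii) else, if the largest-|FC| candidate
#' exceeds `readFrac2` x the maximum reads, take it; (iv) else discard
#' the gene. Each decision path is recorded in the `step` column.
#'
#' @param pairStats data.frame with one row per pair: `gene_id`,
#'   `pair_id`, `total_reads` (summed over all conditions),
#'   `abs_log2fc` (largest absolute log2FC across comparisons), `n_sig`
#'   (number of comparisons significant).
#' @param readFrac1 step (i) read fraction (default 0.15).
#' @param readFrac2 step (iii) read fraction (default 0.30).
#' @param maxReadFallback keep step (ii) enabled (default TRUE).
#' @return data.frame `gene_id`, `pair_id` (`NA` when discarded), `step`
#'   (`"i"`, `"ii"`, `"iii"` or `"discarded"`).
#' @export
selectRepresentativePair <- function(pairStats, readFrac1 = 0.15,
                                     readFrac2 = 0.30,
                                     maxReadFallback = TRUE) {
  need <- c("gene_id", "pair_id", "total_reads", "abs_log2fc", "n_sig")
  if (!all(need %in% names(pairStats)))
    stop("pairStats must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (g in unique(pairStats$gene_id)) {
    ps <- pairStats[pairStats$gene_id == g, , drop = FALSE]
    maxReads <- max(ps$total_reads)
    cand <- ps[ps$n_sig == max(ps$n_sig), , drop = FALSE]
    best <- cand[order(-cand$abs_log2fc, -cand$total_reads, cand$pair_id), ,
                 drop = FALSE][1L, ]
    if (best$total_reads >= readFrac1 * maxReads) {
      sel <- list(gene_id = g, pair_id = best$pair_id, step = "i")
    } else if (maxReadFallback) {
      mr <- ps[order(-ps$total_reads, ps$pair_id), , drop = FALSE][1L, ]
      sel <- list(gene_id = g, pair_id = mr$pair_id, step = "ii")
    } else if (best$total_reads > readFrac2 * maxReads) {
      sel <- list(gene_id = g, pair_id = best$pair_id, step = "iii")
    } else {
      sel <- list(gene_id = g, pair_id = NA_character_, step = "discarded")
    }
    out[[length(out) + 1L]] <- as.data.frame(sel)
  }
  do.call(rbind, out)
}
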