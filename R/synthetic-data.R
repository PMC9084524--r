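#' @name synthetic-data
#' @title Synthetic data generators with planted structure
#' @description Every input type the pipeline consumes can be generated
#'   with known planted effects (motif preferences, donor usage profiles,
#'   genotype effects, polyA usage shifts, delta-PSI events, enriched
#'   genes), so each analysis stage is testable end to end without
#'   external data. All generators are deterministic under a fixed seed.
NULL

.cache <- new.env(parent = emptyenv())

# all 4^7 = 16384 RNA 7-mers, built once per session
.all7mers <- function() {
  if (is.null(.cache$all7mers)) {
    g <- do.call(expand.grid, rep(list(RNA_BASES), 7L))
    .cache$all7mers <- do.call(paste0, g)
  }
  .cache$all7mers
}

#' Simulate a 7-mer Z-score table with planted motif preferences
#'
#' Builds one row per RNA 7-mer (16,384 total). Each kmer's Z-score is
#' the sum of the bonuses of the planted motifs it contains as literal
#' substrings, plus Gaussian noise.
#'
#' @param plantedMotifs named numeric vector, motif -> bonus (motifs <= 7
#'   nt over the RNA alphabet; DNA accepted and converted).
#' @param noiseSd standard deviation of the additive Gaussian noise
#'   (default 0.5; must be non-negative).
#' @param seed integer seed.
#' @param proteinId identifier attached to the table.
#' @return a [KmerZscoreTable-class].
#' @examples
#' tab <- simKmerTable(c(GCUU = 5), noiseSd = 0, seed = 1)
#' motifContribution(tab, "GCUU")  # 1: only GCUU kmers score
#' @export
simKmerTable <- function(plantedMotifs, noiseSd = 0.5, seed = 1L,
                         proteinId = "synthetic") {
  motifs <- .checkMotifs(names(plantedMotifs))
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  set.seed(seed)
  kmers <- .all7mers()
  z <- numeric(length(kmers))
  for (i in seq_along(motifs))
    z <- z + plantedMotifs[[i]] * grepl(motifs[i], kmers, fixed = TRUE)
  if (noiseSd > 0) z <- z + stats::rnorm(length(kmers), 0, noiseSd)
  KmerZscoreTable(stats::setNames(z, kmers), proteinId)
}

#' Simulate junction counts over competing splice donors
#'
#' Draws, for every sample of every group, `depth` reads multinomially
#' over donors according to the group's per-class usage profile (split
#' evenly among a class's donors). Also emits a matching donor
#' annotation and sample grouping.
#'
#' @param profile named list, group -> named numeric vector of class
#'   fractions (classes from `ancestral_long`, `ancestral_short_skip`,
#'   `eutherian_specific`, `lineage_specific`); each profile must sum
#'   to 1.
#' @param depth reads per sample (non-negative).
#' @param nSamples samples per group (default 2).
#' @param donorsPerClass donors annotated per class (default 1).
#' @param seed integer seed.
#' @return list with `counts` (junction data.frame), `annotation`
#'   (donor annotation data.frame) and `grouping` (sample -> group).
#' @export
simJunctionCounts <- function(profile, depth = 10000L, nSamples = 2L,
                              donorsPerClass = 1L, seed = 1L) {
  if (depth < 0) stop("depth must be non-negative")
  for (g in names(profile)) {
    p <- profile[[g]]
    if (abs(sum(p) - 1) > 1e-8)
      stop("profile for group '", g, "' must sum to 1")
    bad <- setdiff(names(p), DONOR_CLASSES)
    if (length(bad)) stop("unknown donor class(es): ",
                          paste(bad, collapse = ", "))
  }
  set.seed(seed)
  donors <- data.frame(
    donor_id = paste0("donor_", seq_len(donorsPerClass * length(DONOR_CLASSES))),
    chrom = "chrX",
    pos = 132413583L + 500L * seq_len(donorsPerClass * length(DONOR_CLASSES)),
    class = rep(DONOR_CLASSES, each = donorsPerClass))
  counts <- data.frame(sample_id = character(), donor_id = character(),
                       acceptor_id = character(), count = integer())
  grouping <- character()
  for (g in names(profile)) {
    pClass <- profile[[g]]
    pDonor <- stats::setNames(numeric(nrow(donors)), donors$donor_id)
    for (cl in names(pClass)) {
      ids <- donors$donor_id[donors$class == cl]
      pDonor[ids] <- pClass[[cl]] / length(ids)
    }
    for (s in seq_len(nSamples)) {
      sid <- paste0(g, "_", s)
      grouping[sid] <- g
      draw <- if (depth > 0)
        as.integer(stats::rmultinom(1L, depth, pDonor)) else
        integer(nrow(donors))
      counts <- rbind(counts, data.frame(
        sample_id = sid, donor_id = donors$donor_id,
        acceptor_id = "acceptor_ref", count = draw))
    }
  }
  rownames(counts) <- NULL
  list(counts = counts, annotation = donors, grouping = grouping)
}

#' Simulate litter-structured placenta/embryo weights
#'
#' Each litter draws a baseline weight from
#' `Normal(baselineMean, baselineSd)`; each animal's weight is the
#' litter baseline plus `effect` if KO plus `Normal(0, noiseSd)` residual
#' noise. Non-positive weights are truncated at 1 mg so litter sizes are
#' preserved. Defaults emulate E18.5 placenta weights (grams) with
#' balanced litters of 8.
#'
#' @param nLitters number of litters (default 6).
#' @param litterSizes integer vector recycled over litters (default 8).
#' @param koPerLitter KO animals per litter (default half the litter,
#'   rounded down); each litter keeps at least one of each genotype.
#' @param baselineMean,baselineSd between-litter baseline distribution
#'   (grams; defaults 0.10 and 0.015).
#' @param effect additive KO effect in grams (default 0, the null).
#' @param noiseSd residual within-litter standard deviation (default
#'   0.012 g).
#' @param tissue tissue label (default `"placenta"`).
#' @param truncateAt floor applied to non-positive weights (grams); set
#'   to `NA` to error instead.
#' @param seed integer seed.
#' @return data.frame with columns `litter_id`, `specimen_id`, `tissue`,
#'   `weight`, `effective_genotype`.
#' @export
simLitterWeights <- function(nLitters = 6L, litterSizes = 8L,
                             koPerLitter = NULL, baselineMean = 0.10,
                             baselineSd = 0.015, effect = 0,
                             noiseSd = 0.012, tissue = "placenta",
                             truncateAt = 1e-3, seed = 1L) {
  if (nLitters < 1L) stop("nLitters must be >= 1")
  sizes <- rep_len(litterSizes, nLitters)
  if (any(sizes < 2L)) stop("litters need at least 2 animals")
  set.seed(seed)
  out <- list()
  for (l in seq_len(nLitters)) {
    n <- sizes[l]
    k <- if (is.null(koPerLitter)) n %/% 2L else min(koPerLitter, n - 1L)
    k <- max(1L, k)
    geno <- c(rep("KO", k), rep("WT", n - k))
    base <- stats::rnorm(1L, baselineMean, baselineSd)
    w <- base + effect * (geno == "KO") + stats::rnorm(n, 0, noiseSd)
    if (any(w <= 0)) {
      if (is.na(truncateAt))
        stop("simulated non-positive weight; enable truncation or adjust ",
             "parameters")
      w[w <= 0] <- truncateAt
    }
    out[[l]] <- data.frame(
      litter_id = sprintf("L%02d", l),
      specimen_id = sprintf("L%02d_%02d", l, seq_len(n)),
      tissue = tissue, weight = w, effective_genotype = geno)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a weight table
#'
#' Dialect: `litter_id specimen_id tissue weight effective_genotype`
#' (tab-separated, header).
#'
#' @param records weight data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeWeightTable <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a weight table written by [writeWeightTable()]
#'
#' @param path path to the TSV.
#' @return data.frame.
#' @export
readWeightTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

# Random background sequence with no polyA-signal hexamer and no A-run of
# >= 4, so synthetic decoys and true sites are the only A-rich features.
.backgroundSeq <- function(n) {
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
              prob = c(0.15, 0.3, 0.3, 0.25))
  seq_ <- paste(s, collapse = "")
  seq_ <- gsub("AAAA+", "CAGT", seq_)
  seq_ <- gsub("AATAAA|ATTAAA", "CGTCGT", seq_)
  # pad back to length after replacements
  while (nchar(seq_) < n)
    seq_ <- paste0(seq_, paste(sample(c("C", "G", "T"), n - nchar(seq_),
                                      replace = TRUE), collapse = ""))
  substr(seq_, 1L, n)
}

#' Simulate 3'-seq reads over two-polyA-site genes
#'
#' Each gene gets its own synthetic chromosome carrying, on the + mRNA
#' strand: a proximal and a distal cleavage site, each with an AATAAA
#' signal 21 nt upstream, and an A-rich decoy tract (A x 18, no signal)
#' where internal priming occurs. Per sample, `depth / nReps` reads per
#' gene are drawn: with probability `ipRate` at the decoy, otherwise at
#' the proximal site with the condition's usage fraction (distal
#' otherwise), with Gaussian positional jitter. Alignment strands are
#' the inverse of the mRNA strand, as in reverse-primed 3'-seq.
#'
#' @param nGenes number of genes / chromosomes (default 4).
#' @param usage named numeric vector, condition -> proximal usage
#'   fraction (default `c(WT = 0.1, KO = 0.9)`), or a list of such
#'   vectors (one per gene) to mix shifted and stable genes.
#' @param depth reads per condition per gene (default 1000), split
#'   evenly over replicates.
#' @param nReps replicates per condition (default 2).
#' @param jitterSd positional jitter standard deviation in nt (default 5).
#' @param ipRate internal-priming fraction (default 0.2).
#' @param siteSpacing distance between proximal and distal sites in nt
#'   (default 400; must be at least 3x the clustering tolerance used
#'   downstream).
#' @param seed integer seed.
#' @return list with `reads` (data.frame `chrom`, `alignment_strand`,
#'   `five_prime_pos`, `sample_id`), `genome`
#'   ([Biostrings::DNAStringSet]), `design` (sample -> condition) and
#'   `truth` (data.frame `gene`, `chrom`, `proximal`, `distal`, `decoy`,
#'   per-condition usage columns).
#' @export
simThreePrimeReads <- function(nGenes = 4L, usage = c(WT = 0.1, KO = 0.9),
                               depth = 1000L, nReps = 2L, jitterSd = 5,
                               ipRate = 0.2, siteSpacing = 400L, seed = 1L) {
  if (depth < 0) stop("depth must be non-negative")
  if (ipRate < 0 || ipRate > 1) stop("ipRate must be in [0, 1]")
  if (!is.list(usage)) usage <- rep(list(usage), nGenes)
  if (length(usage) != nGenes) stop("one usage vector per gene required")
  conds <- names(usage[[1L]])
  set.seed(seed)
  signal <- "AATAAA"
  prox <- 501L; dist <- prox + siteSpacing
  decoy <- dist + 300L
  chromLen <- decoy + 100L
  seqs <- character(nGenes)
  truth <- list()
  reads <- list()
  perRep <- max(0L, as.integer(round(depth / nReps)))
  for (g in seq_len(nGenes)) {
    chrom <- sprintf("synth_gene_%02d", g)
    s <- .backgroundSeq(chromLen)
    put <- function(s, at, frag) {
      paste0(substr(s, 1L, at - 1L), frag,
             substr(s, at + nchar(frag), nchar(s)))
    }
    # signals 21 nt upstream of each true cleavage site (within the
    # default 10-40 nt search window)
    s <- put(s, prox - 26L, signal)
    s <- put(s, dist - 26L, signal)
    # decoy: A18 tract starting at the decoy point; scrub any signal-like
    # context upstream of it
    s <- put(s, decoy - 40L, paste(rep("C", 40L), collapse = ""))
    s <- put(s, decoy, paste(rep("A", 18L), collapse = ""))
    seqs[g] <- s
    for (cond in conds) {
      for (r in seq_len(nReps)) {
        sid <- paste0(cond, "_", r)
        if (perRep == 0L) next
        isIp <- stats::runif(perRep) < ipRate
        isProx <- stats::runif(perRep) < usage[[g]][cond]
        site <- ifelse(isIp, decoy, ifelse(isProx, prox, dist))
        pos <- as.integer(round(site + stats::rnorm(perRep, 0, jitterSd)))
        pos <- pmax(1L, pmin(chromLen, pos))
        reads[[length(reads) + 1L]] <- data.frame(
          chrom = chrom, alignment_strand = "-",  # mRNA strand is +
          five_prime_pos = pos, sample_id = sid)
      }
    }
    truth[[g]] <- data.frame(gene = sprintf("gene_%02d", g), chrom = chrom,
                             proximal = prox, distal = dist, decoy = decoy,
                             t(usage[[g]]))
  }
  design <- stats::setNames(rep(conds, each = nReps),
                            paste0(rep(conds, each = nReps),
                                   "_", rep(seq_len(nReps), length(conds))))
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs, sprintf(
    "synth_gene_%02d", seq_len(nGenes))))
  list(reads = do.call(rbind, reads) %||%
         data.frame(chrom = character(), alignment_strand = character(),
                    five_prime_pos = integer(), sample_id = character()),
       genome = genome, design = design, truth = do.call(rbind, truth))
}

#' Simulate a PSI table with planted differential events
#'
#' `nDiff` events get a planted KO-minus-WT delta-PSI drawn from `dpsi`
#' (random sign), `nNull` events none. Baseline WT PSI is uniform on
#' `baselineRange`; per-sample Gaussian measurement noise is added and
#' values are clipped to \[0, 100\]. Coverage scores are sampled from
#' `coverageProbs` (by default every event passes the LOW filter,
#' mirroring tables already restricted to covered events).
#'
#' @param nDiff number of planted differential events (default 50).
#' @param nNull number of unchanged events (default 200).
#' @param dpsi numeric vector of planted |delta-PSI| magnitudes sampled
#'   per event (default 20).
#' @param noiseSd per-sample PSI noise standard deviation (default 3).
#' @param nReps replicates per condition (default 2).
#' @param baselineRange uniform range of WT baseline PSI (default
#'   c(25, 65), keeping planted shifts clear of the 0/100 bounds).
#' @param coverageProbs named probabilities over the ordinal scale
#'   N, VLOW, LOW, OK, SOK.
#' @param seed integer seed.
#' @return list with `psi` (data.frame in the [readPsiTable()] layout)
#'   and `truth` (data.frame `event_id`, `planted_dpsi`).
#' @export
simPsiTable <- function(nDiff = 50L, nNull = 200L, dpsi = 20,
                        noiseSd = 3, nReps = 2L,
                        baselineRange = c(25, 65),
                        coverageProbs = c(N = 0, VLOW = 0, LOW = 0.2,
                                          OK = 0.5, SOK = 0.3),
                        seed = 1L) {
  if (nReps < 1L) stop("nReps must be >= 1")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  set.seed(seed)
  n <- nDiff + nNull
  planted <- c(dpsi[sample.int(length(dpsi), nDiff, replace = TRUE)] *
                 sample(c(-1, 1), nDiff, replace = TRUE),
               rep(0, nNull))
  base <- stats::runif(n, baselineRange[1L], baselineRange[2L])
  # keep shifted values inside [0, 100]
  base <- pmin(pmax(base, pmax(0, -planted)), 100 - pmax(0, planted))
  samples <- c(paste0("WT_", seq_len(nReps)), paste0("KO_", seq_len(nReps)))
  psi <- data.frame(event_id = sprintf("ev_%04d", seq_len(n)),
                    gene = sprintf("gene_%04d", seq_len(n)),
                    chrom = "chr1",
                    span = paste0(seq_len(n) * 1000L, "-",
                                  seq_len(n) * 1000L + 100L))
  for (s in samples) {
    mu <- base + ifelse(rep(grepl("^KO", s), n), planted, 0)
    psi[[paste0("psi.", s)]] <-
      pmin(100, pmax(0, mu + stats::rnorm(n, 0, noiseSd)))
  }
  for (s in samples) {
    psi[[paste0("q.", s)]] <- sample(names(coverageProbs), n, replace = TRUE,
                                     prob = coverageProbs)
  }
  list(psi = psi,
       truth = data.frame(event_id = psi$event_id, planted_dpsi = planted))
}

#' Simulate a TPM matrix with planted target-enriched genes
#'
#' Baseline per-gene expression is log-normal; the first `nEnriched`
#' genes are multiplied by `foldChange` in the target group. Log-normal
#' multiplicative measurement noise with log-sd `noiseSdLog` is applied
#' per sample (0 for exact recovery).
#'
#' @param nGenes number of genes (default 197, a splicing-factor-sized
#'   panel).
#' @param nEnriched planted target-enriched genes (default 7).
#' @param foldChange planted enrichment fold change (default 8).
#' @param groups named integer vector, group -> number of samples.
#' @param targetGroup the enriched group (default `"placenta"`).
#' @param baseMeanLog,baseSdLog log-normal baseline parameters (defaults
#'   log(30) and 0.8).
#' @param noiseSdLog per-sample log-normal noise sd (default 0.1).
#' @param seed integer seed.
#' @return list with `tpm` (matrix), `groups` (sample -> group) and
#'   `truth` (character vector of planted enriched genes).
#' @export
simExpressionMatrix <- function(nGenes = 197L, nEnriched = 7L,
                                foldChange = 8,
                                groups = c(placenta = 3L, brain = 3L,
                                           muscle = 3L, liver = 3L),
                                targetGroup = "placenta",
                                baseMeanLog = log(30), baseSdLog = 0.8,
                                noiseSdLog = 0.1, seed = 1L) {
  if (!targetGroup %in% names(groups)) stop("target group not in groups")
  set.seed(seed)
  samples <- unlist(lapply(names(groups), function(g)
    paste0(g, "_", seq_len(groups[[g]]))))
  grp <- stats::setNames(rep(names(groups), unname(groups)), samples)
  base <- stats::rlnorm(nGenes, baseMeanLog, baseSdLog)
  genes <- sprintf("sf_%03d", seq_len(nGenes))
  tpm <- matrix(0, nGenes, length(samples),
                dimnames = list(genes, samples))
  for (s in samples) {
    mu <- base * ifelse(seq_len(nGenes) <= nEnriched & grp[s] == targetGroup,
                        foldChange, 1)
    noise <- if (noiseSdLog > 0)
      stats::rlnorm(nGenes, 0, noiseSdLog) else 1
    tpm[, s] <- mu * noise
  }
  list(tpm = tpm, groups = grp, truth = genes[seq_len(nEnriched)])
}
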