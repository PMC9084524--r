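test_that("cleavage inference inverts the alignment strand", {
  reads <- data.frame(chrom = c("c1", "c1"),
                      alignment_strand = c("+", "-"),
                      five_prime_pos = c(1000L, 2000L),
                      sample_id = "s1")
  cl <- inferCleavageSites(reads)
  expect_equal(cl$mrna_strand, c("-", "+"))
  expect_equal(cl$position, c(1000L, 2000L))
})

test_that("BED6 reads convert to 1-based 5'-end records and round-trip", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("c1\t999\t1049\ts1\t0\t+",
               "c1\t1951\t2000\ts1\t0\t-",
               "c2\t10\t60\ts2\t0\t+",
               "c2\t100\t150\ts2\t0\t-"), path)
  reads <- readThreePrimeReads(path)
  expect_equal(reads$five_prime_pos, c(1000L, 2000L, 11L, 150L))
  # hand table of inferred sites
  cl <- inferCleavageSites(reads)
  expect_equal(cl$mrna_strand, c("-", "+", "-", "+"))
  # TSV round trip
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeThreePrimeReads(reads, tsv, format = "tsv")
  back <- readThreePrimeReads(tsv)
  expect_equal(back, reads)
})

test_that("greedy clustering calls peaks and partitions reads", {
  # all reads at one position
  cl <- data.frame(chrom = "c1", mrna_strand = "+",
                   position = rep(500L, 7), sample_id = "s1")
  sites <- callSites(cl, tolerance = 50)
  expect_equal(length(sites), 1L)
  expect_equal(GenomicRanges::start(sites), 500L)
  expect_equal(sites$support, 7L)
  # two clusters 200 nt apart resolve to the two modes
  cl2 <- data.frame(chrom = "c1", mrna_strand = "+",
                    position = c(rep(500L, 5), 498L, rep(700L, 4), 703L),
                    sample_id = "s1")
  sites2 <- callSites(cl2, tolerance = 50)
  expect_equal(sort(GenomicRanges::start(sites2)), c(500L, 700L))
  expect_equal(sum(sites2$support), 11L)  # every read assigned exactly once
  # reads spread within the tolerance collapse onto the max-support mode
  cl3 <- data.frame(chrom = "c1", mrna_strand = "+",
                    position = c(480L, rep(500L, 3), 510L, 530L),
                    sample_id = "s1")
  sites3 <- callSites(cl3, tolerance = 50)
  expect_equal(GenomicRanges::start(sites3), 500L)
  expect_equal(sites3$support, 6L)
  # empty input
  expect_equal(length(callSites(cl[0, , drop = FALSE])), 0L)
})

test_that("called sites are pairwise more than tolerance apart", {
  set.seed(13)
  cl <- data.frame(chrom = "c1", mrna_strand = "+",
                   position = sample(1:2000, 500, replace = TRUE),
                   sample_id = "s1")
  sites <- callSites(cl, tolerance = 50)
  pos <- sort(GenomicRanges::start(sites))
  if (length(pos) > 1) expect_true(all(diff(pos) > 50))
})

test_that("internal-priming filter keeps signal sites, removes A tracts", {
  # chromosome: AATAAA ends 25 nt upstream of cleavage at 100; mixed
  # downstream.  decoy at 300 sits at the start of an A18 tract with a
  # C/G/T-only upstream window.
  seqchars <- rep("C", 400)
  seqchars[70:75] <- strsplit("AATAAA", "")[[1]]          # signal for site 100
  seqchars[101:120] <- rep(c("G", "T"), 10)               # benign downstream
  seqchars[301:318] <- "A"                                # decoy tract
  genome <- Biostrings::DNAStringSet(c(c1 = paste(seqchars, collapse = "")))
  sites <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(100L, 300L),
                                                         width = 1L), "+",
                                  support = c(10L, 5L))
  kept <- filterInternalPriming(sites, genome)
  expect_equal(GenomicRanges::start(kept), 100L)
  removed <- attr(kept, "removed")
  expect_equal(nrow(removed), 1L)
  expect_match(removed$reason, "A-rich")
  # empty input passes through
  expect_equal(length(filterInternalPriming(sites[0], genome)), 0L)
  # missing chromosome is an error
  badSites <- GenomicRanges::GRanges("cX", IRanges::IRanges(5L, width = 1L),
                                     "+", support = 1L)
  expect_error(filterInternalPriming(badSites, genome), "lacks sequence")
})

test_that("a site without signal but benign downstream context is kept", {
  genome <- Biostrings::DNAStringSet(c(c1 = paste(rep("CGT", 100),
                                                  collapse = "")))
  sites <- GenomicRanges::GRanges("c1", IRanges::IRanges(150L, width = 1L),
                                  "+", support = 3L)
  expect_equal(length(filterInternalPriming(sites, genome)), 1L)
})

test_that("proximal usage percent behaves at the boundaries", {
  cnt <- rbind(proximal = c(s1 = 0, s2 = 25, s3 = 0),
               distal = c(s1 = 50, s2 = 25, s3 = 0))
  pair <- PolyAPair("g", "c1", "+", 100, 600, cnt)
  pu <- proximalUsage(pair)
  expect_equal(unname(pu["s1"]), 0)
  expect_equal(unname(pu["s2"]), 50)
  expect_true(is.na(pu["s3"]))
  expect_error(proximalUsage(pair, "nope"), "unknown sample")
})

test_that("pair orientation is validated in mRNA coordinates", {
  cnt <- rbind(proximal = c(s1 = 1), distal = c(s1 = 1))
  expect_error(PolyAPair("g", "c1", "+", 600, 100, cnt), "5'")
  # on the minus strand the proximal site has the larger coordinate
  expect_s4_class(PolyAPair("g", "c1", "-", 600, 100, cnt), "PolyAPair")
})

mkPair <- function(id, prox, dist) {
  cnt <- rbind(proximal = prox, distal = dist)
  colnames(cnt) <- names(prox)
  PolyAPair(id, "c1", "+", 100, 600, cnt)
}

test_that("pair testing labels usage shifts and ignores pure scaling", {
  design <- c(WT_1 = "WT", WT_2 = "WT", KO_1 = "KO", KO_2 = "KO")
  # identical proximal fractions: ns, log2FC 0
  flat <- mkPair("flat", c(WT_1 = 50, WT_2 = 50, KO_1 = 50, KO_2 = 50),
                 c(WT_1 = 50, WT_2 = 50, KO_1 = 50, KO_2 = 50))
  # planted 10% -> 90% usage shift at depth 1000/condition
  shift <- mkPair("shift", c(WT_1 = 50, WT_2 = 50, KO_1 = 450, KO_2 = 450),
                  c(WT_1 = 450, WT_2 = 450, KO_1 = 50, KO_2 = 50))
  # both sites doubled: usage unchanged, must stay ns
  scaled <- mkPair("scaled", c(WT_1 = 100, WT_2 = 100, KO_1 = 200, KO_2 = 200),
                   c(WT_1 = 300, WT_2 = 300, KO_1 = 600, KO_2 = 600))
  res <- testPairs(list(flat = flat, shift = shift, scaled = scaled), design)
  expect_equal(res$status[res$pair_id == "flat"], "ns")
  expect_equal(res$log2fc[res$pair_id == "flat"], 0)
  expect_equal(res$status[res$pair_id == "shift"], "enhanced")
  expect_lt(res$fdr[res$pair_id == "shift"], 0.1)
  expect_equal(res$status[res$pair_id == "scaled"], "ns")
  expect_equal(res$log2fc[res$pair_id == "scaled"], 0)
  # Fisher oracle on the summed 2x2 for the shifted pair
  p <- fisher.test(matrix(c(900, 100, 100, 900), 2))$p.value
  expect_equal(res$p[res$pair_id == "shift"], p)
})

test_that("degenerate 2x2 tables are continuity-corrected and flagged", {
  design <- c(WT_1 = "WT", KO_1 = "KO")
  deg <- mkPair("deg", c(WT_1 = 0, KO_1 = 30), c(WT_1 = 40, KO_1 = 10))
  res <- testPairs(list(deg = deg), design)
  expect_true(res$degenerate)
  expect_true(is.finite(res$log2fc))
  expect_gt(res$log2fc, 0)
})

test_that("externally supplied FDRs override the built-in test", {
  design <- c(WT_1 = "WT", KO_1 = "KO")
  pair <- mkPair("p1", c(WT_1 = 10, KO_1 = 90), c(WT_1 = 90, KO_1 = 10))
  ext <- data.frame(pair_id = "p1", comparison = "KO", fdr = 0.9)
  res <- testPairs(list(p1 = pair), design, fdrTable = ext)
  expect_equal(res$fdr, 0.9)
  expect_equal(res$status, "ns")
})

test_that("representative-pair selection follows the ranked rules", {
  # single pair: selected via (i)
  one <- data.frame(gene_id = "g1", pair_id = "p1", total_reads = 100,
                    abs_log2fc = 1, n_sig = 0)
  expect_equal(selectRepresentativePair(one)$step, "i")
  # A significant in 2 comparisons with |FC|=2 and 200 reads beats B
  # (1 comparison, 1000 reads): 200 >= 0.15 * 1000
  two <- data.frame(gene_id = "g2", pair_id = c("A", "B"),
                    total_reads = c(200, 1000), abs_log2fc = c(2, 3),
                    n_sig = c(2, 1))
  sel <- selectRepresentativePair(two)
  expect_equal(sel$pair_id, "A")
  expect_equal(sel$step, "i")
  # candidate with 10% of max reads falls through to the max-read pair
  low <- data.frame(gene_id = "g3", pair_id = c("A", "B"),
                    total_reads = c(100, 1000), abs_log2fc = c(2, 0.1),
                    n_sig = c(2, 1))
  sel2 <- selectRepresentativePair(low)
  expect_equal(sel2$pair_id, "B")
  expect_equal(sel2$step, "ii")
  # with the fallback disabled, 10% < 30% leads to a discard ...
  sel3 <- selectRepresentativePair(low, maxReadFallback = FALSE)
  expect_equal(sel3$step, "discarded")
  expect_true(is.na(sel3$pair_id))
  # ... and step (iii) recovers a moderately covered candidate when the
  # step (i) read requirement is set above the step (iii) one
  mid <- data.frame(gene_id = "g4", pair_id = c("A", "B"),
                    total_reads = c(350, 1000), abs_log2fc = c(2, 0.1),
                    n_sig = c(2, 1))
  sel4 <- selectRepresentativePair(mid, readFrac1 = 0.5,
                                   maxReadFallback = FALSE)
  expect_equal(sel4$pair_id, "A")
  expect_equal(sel4$step, "iii")
})

test_that("a planted near-0% to ~50% usage shift is recovered end to end", {
  # emulates a proximal site silent in WT and used in half the
  # transcripts of the double-KO (synthetic counts, not real data)
  sim <- simThreePrimeReads(nGenes = 1,
                            usage = c(WT = 0.01, DKO = 0.5),
                            depth = 2000, jitterSd = 2, ipRate = 0,
                            seed = 31)
  cl <- inferCleavageSites(sim$reads)
  sites <- callSites(cl, tolerance = 50, minSupport = 5)
  sites <- filterInternalPriming(sites, sim$genome)
  cnt <- siteCounts(sites, cl, tolerance = 50)
  pair <- buildGenePair(sites, cnt, "gene_01", sim$truth$chrom[1])
  pu <- proximalUsage(pair)
  wt <- mean(pu[grep("^WT", names(pu))])
  dko <- mean(pu[grep("^DKO", names(pu))])
  expect_lt(wt, 5)
  expect_lt(abs(dko - 50), 5)
})
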