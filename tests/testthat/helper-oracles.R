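# Independent brute-force oracles used to validate the fast paths. They
# deliberately avoid the package's own helpers: selection is done by
# repeated scans, substring matching by explicit position loops.

oracleTopKmers <- function(z, n) {
  # repeated max-extraction instead of a single sort; ties resolved by
  # scanning the tied kmers for the lexicographic minimum
  kmer <- names(z)
  z <- unname(z)
  out_k <- character(0); out_z <- numeric(0)
  while (length(z) > 0 && length(out_k) < n) {
    tied <- which(z == max(z))
    best <- tied[which.min(match(kmer[tied], sort(kmer[tied])))]
    out_k <- c(out_k, kmer[best]); out_z <- c(out_z, z[best])
    kmer <- kmer[-best]; z <- z[-best]
  }
  data.frame(kmer = out_k, zscore = out_z)
}

oracleContains <- function(kmer, motif) {
  lk <- nchar(kmer); lm <- nchar(motif)
  if (lm > lk) return(FALSE)
  for (i in seq_len(lk - lm + 1)) {
    if (substr(kmer, i, i + lm - 1) == motif) return(TRUE)
  }
  FALSE
}

oracleMotifContribution <- function(z, motifs, n) {
  top <- oracleTopKmers(z, n)
  num <- 0
  for (i in seq_len(nrow(top))) {
    hit <- FALSE
    for (m in motifs) if (oracleContains(top$kmer[i], m)) hit <- TRUE
    if (hit) num <- num + top$zscore[i]
  }
  num / sum(top$zscore)
}

oracleGcPartition <- function(z, n) {
  top <- oracleTopKmers(z, n)
  sums <- c(A = 0, C = 0, G = 0, U = 0)
  for (i in seq_len(nrow(top))) {
    k <- top$kmer[i]
    pos <- integer(0)
    for (j in seq_len(nchar(k) - 2)) {
      if (substr(k, j, j + 1) == "GC") pos <- c(pos, j)
    }
    if (length(pos) != 1) next
    b <- substr(k, pos + 2, pos + 2)
    sums[b] <- sums[b] + top$zscore[i]
  }
  if (sum(sums) <= 0) return(rep(NA_real_, 4))  # partition undefined
  sums / sum(sums)
}

oracleGcSpacing <- function(z, n) {
  top <- oracleTopKmers(z, n)
  s1 <- 0; s2 <- 0; h1 <- FALSE; h2 <- FALSE
  for (i in seq_len(nrow(top))) {
    k <- top$kmer[i]
    m1 <- FALSE; m2 <- FALSE
    for (j in seq_len(max(0, nchar(k) - 4))) {
      if (substr(k, j, j + 1) == "GC" && substr(k, j + 3, j + 4) == "GC")
        m1 <- TRUE
    }
    for (j in seq_len(max(0, nchar(k) - 5))) {
      if (substr(k, j, j + 1) == "GC" && substr(k, j + 4, j + 5) == "GC")
        m2 <- TRUE
    }
    if (m1) { s1 <- s1 + top$zscore[i]; h1 <- TRUE }
    if (m2) { s2 <- s2 + top$zscore[i]; h2 <- TRUE }
  }
  if (!h1 || !h2 || s1 <= 0 || s2 <= 0) return(NA_real_)
  log2(s1 / s2)
}

# a random named Z-score vector over distinct 7-mers
KMER_POOL <- do.call(paste0,
                     do.call(expand.grid, rep(list(c("A", "C", "G", "U")), 7)))

randomKmerZ <- function(nrow, meanZ = 2, sdZ = 3) {
  k <- sample(KMER_POOL, nrow)
  stats::setNames(stats::rnorm(nrow, meanZ, sdZ), k)
}

# Full enumeration of the litter permutation p-value over the product
# space of within-litter labelings (small configurations only).
oracleLitterExactP <- function(ranksList, koList, alternative) {
  obs <- 0
  for (i in seq_along(ranksList))
    obs <- obs + sum(ranksList[[i]][koList[[i]]])
  choicesPerLitter <- lapply(seq_along(ranksList), function(i)
    utils::combn(seq_along(ranksList[[i]]), length(koList[[i]]),
                 simplify = FALSE))
  idx <- expand.grid(lapply(choicesPerLitter, seq_along))
  stats <- apply(idx, 1, function(row) {
    s <- 0
    for (i in seq_along(ranksList))
      s <- s + sum(ranksList[[i]][choicesPerLitter[[i]][[row[i]]]])
    s
  })
  if (alternative == "ko_heavier") mean(stats >= obs - 1e-9)
  else mean(stats <= obs + 1e-9)
}
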