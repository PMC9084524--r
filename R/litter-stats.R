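#' Effective genotype from raw alleles and parental origin
#'
#' Collapses raw allele pairs into the effective WT/KO classification used
#' for weight analyses. For the X-linked, placentally imprinted gene
#' (Mbnl3-like, `xLinked = TRUE`) paternal-X silencing in trophoblast
#' means parental origin matters:
#' \itemize{
#'   \item heterozygous female with a WT maternal allele: effectively WT
#'     (the KO paternal allele is not expressed in placenta);
#'   \item heterozygous female with a KO maternal allele and WT paternal
#'     allele: KO in the placental context (the expressed maternal copy is
#'     lost), unresolvable (`excluded`) in the constitutive context;
#'   \item homozygous / hemizygous KO: KO. Males are hemizygous, so the
#'     maternal allele decides.
#' }
#' For an autosomal paralog (Mbnl2-like, `xLinked = FALSE`) heterozygotes
#' are treated as WT.
#'
#' @param maternalAllele,paternalAllele `"+"` (WT) or `"-"` (KO); for
#'   X-linked genes in males the paternal slot is the Y (`NA` or `"Y"`).
#' @param sex `"F"`, `"M"` or `"unknown"`.
#' @param xLinked is the gene X-linked with placental paternal-X silencing?
#' @param context `"constitutive"` or `"placental"`.
#' @return one of `"WT"`, `"KO"`, `"excluded"`.
#' @export
effectiveGenotype <- function(maternalAllele, paternalAllele,
                              sex = c("F", "M", "unknown"),
                              xLinked = TRUE,
                              context = c("constitutive", "placental")) {
  sex <- match.arg(sex)
  context <- match.arg(context)
  ok <- function(a) !is.na(a) && a %in% c("+", "-")
  if (!xLinked) {
    if (!ok(maternalAllele) || !ok(paternalAllele))
      stop("both alleles must be '+' or '-' for an autosomal gene")
    n_ko <- (maternalAllele == "-") + (paternalAllele == "-")
    return(if (n_ko == 2L) "KO" else "WT")  # het counts as WT
  }
  if (!ok(maternalAllele))
    stop("X-linked genotype requires a known maternal allele (parental origin)")
  if (sex == "M" || (!is.na(paternalAllele) && paternalAllele == "Y"))
    return(if (maternalAllele == "-") "KO" else "WT")
  if (sex == "unknown") return("excluded")
  if (!ok(paternalAllele))
    stop("X-linked female genotype requires a known paternal allele")
  if (maternalAllele == "+" && paternalAllele == "+") return("WT")
  if (maternalAllele == "-" && paternalAllele == "-") return("KO")
  if (maternalAllele == "+") return("WT")  # het, WT maternal allele
  # maternal KO / paternal WT: expressed copy lost only where the paternal
  # X is silenced
  if (context == "placental") "KO" else "excluded"
}

#' Assign effective genotypes across a weight table
#'
#' Row-wise wrapper around [effectiveGenotype()].
#'
#' @param records data.frame with columns `maternal_allele`,
#'   `paternal_allele`, `sex`.
#' @param xLinked,context passed to [effectiveGenotype()].
#' @return `records` with an `effective_genotype` column.
#' @export
assignEffectiveGenotype <- function(records, xLinked = TRUE,
                                    context = c("constitutive", "placental")) {
  context <- match.arg(context)
  records$effective_genotype <- vapply(seq_len(nrow(records)), function(i)
    effectiveGenotype(records$maternal_allele[i], records$paternal_allele[i],
                      records$sex[i], xLinked, context), character(1L))
  records
}

# Exact distribution of the KO rank-sum for one litter: all C(n, k)
# labelings of k KO animals over ranks r. Returns a named count vector
# (names are statistic values).
.litterRankSumDist <- function(r, k) {
  sums <- utils::combn(r, k, sum)
  tab <- table(sums)
  stats::setNames(as.numeric(tab), names(tab))
}

# Convolve two value->count distributions (independent litters).
.convolveDist <- function(d1, d2) {
  v1 <- as.numeric(names(d1)); v2 <- as.numeric(names(d2))
  vals <- outer(v1, v2, `+`)
  cnts <- outer(unname(d1), unname(d2))
  agg <- tapply(as.vector(cnts), as.vector(vals), sum)
  stats::setNames(as.numeric(agg), names(agg))
}

.prepLitters <- function(records, tissue) {
  need <- c("litter_id", "weight", "effective_genotype")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (!is.null(tissue)) {
    if (!"tissue" %in% names(records)) stop("no 'tissue' column to filter on")
    records <- records[records$tissue == tissue, , drop = FALSE]
  }
  records <- records[records$effective_genotype %in% c("WT", "KO"), ,
                     drop = FALSE]
  split(records, records$litter_id)
}

#' Within-litter rank permutation test for a genotype effect on weight
#'
#' Ranks each animal's weight within its litter (ascending, mid-ranks for
#' ties) and sums the KO ranks across litters. Genotype labels are then
#' permuted independently within each litter, preserving the per-litter
#' genotype counts (the litter is the exchangeable unit), and the p-value
#' is the fraction of permutations with a KO rank-sum at least as extreme
#' as observed in the stated direction. When the number of distinct
#' labelings is small (`exact = "auto"`, at most `exactLimit`) the full
#' enumeration replaces Monte Carlo sampling; litters are independent, so
#' the enumeration is done per litter and the rank-sum distributions
#' convolved.
#'
#' Litters containing a single genotype carry no within-litter contrast
#' and are dropped with a warning.
#'
#' @param records data.frame with columns `litter_id`, `weight`,
#'   `effective_genotype` (and optionally `tissue`).
#' @param tissue optional tissue to filter on (e.g. `"placenta"`).
#' @param nIter Monte Carlo permutations (default 1000).
#' @param seed integer seed for the Monte Carlo draw.
#' @param alternative `"ko_heavier"` (KO rank-sum at least the observed) or
#'   `"ko_lighter"`.
#' @param exact `"auto"` (enumerate when feasible), `"on"`, or `"off"`.
#' @param exactLimit labeling-count ceiling for automatic enumeration.
#' @param includeObserved count the observed labeling as one Monte Carlo
#'   iteration (adds 1 to both numerator and denominator).
#' @param smooth use the (count + 1) / (nIter + 1) p-value estimate.
#' @return a [PermutationResult-class].
#' @examples
#' d <- data.frame(litter_id = "L1", weight = 1:6,
#'                 effective_genotype = rep(c("WT", "KO"), each = 3))
#' pvalue(litterRankPermutationTest(d, alternative = "ko_heavier"))  # 0.05
#' @export
litterRankPermutationTest <- function(records, tissue = NULL, nIter = 1000L,
                                      seed = NULL,
                                      alternative = c("ko_heavier", "ko_lighter"),
                                      exact = c("auto", "on", "off"),
                                      exactLimit = 1e6,
                                      includeObserved = FALSE,
                                      smooth = FALSE) {
  alternative <- match.arg(alternative)
  exact <- match.arg(exact)
  if (nIter < 1L) stop("nIter must be >= 1")
  litters <- .prepLitters(records, tissue)
  dropped <- names(litters)[vapply(litters, function(l)
    length(unique(l$effective_genotype)) < 2L, logical(1L))]
  if (length(dropped)) {
    warning("dropping litter(s) with a single genotype: ",
            paste(dropped, collapse = ", "))
    litters <- litters[setdiff(names(litters), dropped)]
  }
  if (length(litters) == 0L)
    stop("no litter contains both genotypes")

  ranks <- lapply(litters, function(l) rank(l$weight))  # mid-ranks for ties
  kos <- vapply(litters, function(l)
    sum(l$effective_genotype == "KO"), integer(1L))
  observed <- sum(vapply(seq_along(litters), function(i)
    sum(ranks[[i]][litters[[i]]$effective_genotype == "KO"]), numeric(1L)))

  nLabelings <- prod(vapply(seq_along(litters), function(i)
    choose(length(ranks[[i]]), kos[i]), numeric(1L)))
  useExact <- exact == "on" || (exact == "auto" && nLabelings <= exactLimit)
  eps <- 1e-9

  if (useExact) {
    dist <- Reduce(.convolveDist, lapply(seq_along(litters), function(i)
      .litterRankSumDist(ranks[[i]], kos[i])))
    vals <- as.numeric(names(dist))
    extreme <- if (alternative == "ko_heavier") vals >= observed - eps
               else vals <= observed + eps
    nExtreme <- sum(dist[extreme])
    res <- new("PermutationResult", observed = observed, nIter = nLabelings,
               nAsExtreme = nExtreme, p = nExtreme / nLabelings,
               seed = NA_integer_, alternative = alternative,
               method = "exact", littersUsed = names(litters),
               littersDropped = as.character(dropped))
    return(res)
  }

  if (!is.null(seed)) set.seed(seed)
  perm <- numeric(nIter)
  for (i in seq_along(litters)) {
    r <- ranks[[i]]; k <- kos[i]
    perm <- perm + vapply(seq_len(nIter), function(j) sum(sample(r, k)),
                          numeric(1L))
  }
  nExtreme <- if (alternative == "ko_heavier") sum(perm >= observed - eps)
              else sum(perm <= observed + eps)
  if (includeObserved) {
    nExtreme <- nExtreme + 1
    nIter <- nIter + 1
  }
  p <- if (smooth) (nExtreme + 1) / (nIter + 1) else nExtreme / nIter
  new("PermutationResult", observed = observed, nIter = nIter,
      nAsExtreme = nExtreme, p = min(p, 1), seed = as.integer(seed %||% NA),
      alternative = alternative, method = "montecarlo",
      littersUsed = names(litters), littersDropped = as.character(dropped))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize weights within litters
#'
#' Divides each animal's weight by the average of the mean WT and mean KO
#' weights within its litter, removing the large between-litter baseline
#' variability while keeping the genotype contrast. By construction,
#' within every retained litter
#' `(mean normalized WT + mean normalized KO) / 2 = 1` exactly. Litters
#' with fewer than `minPerGenotype` animals of either genotype are
#' excluded and reported.
#'
#' @param records data.frame with columns `litter_id`, `weight`,
#'   `effective_genotype` (and optionally `tissue`).
#' @param tissue optional tissue filter.
#' @param minPerGenotype minimum WT and KO animals per litter (default 3,
#'   the calorie-restriction workflow's rule; set lower for designs that
#'   pool smaller litters).
#' @return the passing records with a `normalized_weight` column.
#' @export
normalizeWithinLitter <- function(records, tissue = NULL, minPerGenotype = 3L) {
  litters <- .prepLitters(records, tissue)
  pass <- vapply(litters, function(l)
    sum(l$effective_genotype == "WT") >= minPerGenotype &&
    sum(l$effective_genotype == "KO") >= minPerGenotype, logical(1L))
  if (any(!pass))
    message("excluding litter(s) below the ", minPerGenotype,
            "-per-genotype minimum: ",
            paste(names(litters)[!pass], collapse = ", "))
  litters <- litters[pass]
  if (length(litters) == 0L)
    stop("no litter passes the per-genotype minimum")
  out <- lapply(litters, function(l) {
    denom <- (mean(l$weight[l$effective_genotype == "WT"]) +
              mean(l$weight[l$effective_genotype == "KO"])) / 2
    l$normalized_weight <- l$weight / denom
    l
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Placental efficiency (embryo weight / placenta weight)
#'
#' @param embryo data.frame of embryo records with columns `specimen_id`
#'   and `weight` (grams).
#' @param placenta matching placenta records; the specimen sets must be
#'   identical and placenta weights positive.
#' @return named numeric vector of unitless embryo/placenta ratios.
#' @export
placentalEfficiency <- function(embryo, placenta) {
  stopifnot(all(c("specimen_id", "weight") %in% names(embryo)),
            all(c("specimen_id", "weight") %in% names(placenta)))
  if (!setequal(embryo$specimen_id, placenta$specimen_id) ||
      anyDuplicated(embryo$specimen_id) || anyDuplicated(placenta$specimen_id))
    stop("embryo and placenta records must cover the same specimens exactly once")
  m <- match(embryo$specimen_id, placenta$specimen_id)
  pw <- placenta$weight[m]
  if (any(pw <= 0)) stop("placenta weight must be > 0")
  stats::setNames(embryo$weight / pw, embryo$specimen_id)
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Exact by enumeration of all rank assignments (mid-ranks for ties) when
#' the combined sample size is at most 20; normal approximation with tie
#' correction and continuity correction otherwise.
#'
#' @param a,b numeric vectors of measurements.
#' @return list with `statistic` (rank-sum W of `a`) and `p.value`.
#' @export
rankSumCompare <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  sa <- sum(r[seq_along(a)])
  W <- sa - length(a) * (length(a) + 1) / 2
  if (n <= 20L) {
    ea <- length(a) * (n + 1) / 2
    sums <- utils::combn(r, length(a), sum)
    p <- mean(abs(sums - ea) >= abs(sa - ea) - 1e-9)
  } else {
    p <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  }
  list(statistic = W, p.value = p)
}
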