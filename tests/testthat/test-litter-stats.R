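test_that("effective genotype applies parental-origin rules", {
  # X-linked het female with WT maternal allele is effectively WT
  expect_equal(effectiveGenotype("+", "-", "F", xLinked = TRUE), "WT")
  # maternal-KO / paternal-WT female: KO in placenta, unresolvable
  # constitutively
  expect_equal(effectiveGenotype("-", "+", "F", xLinked = TRUE,
                                 context = "placental"), "KO")
  expect_equal(effectiveGenotype("-", "+", "F", xLinked = TRUE,
                                 context = "constitutive"), "excluded")
  expect_equal(effectiveGenotype("-", "-", "F", xLinked = TRUE), "KO")
  # hemizygous male follows the maternal allele
  expect_equal(effectiveGenotype("-", "Y", "M", xLinked = TRUE), "KO")
  expect_equal(effectiveGenotype("+", "Y", "M", xLinked = TRUE), "WT")
  # autosomal paralog: heterozygotes count as WT
  expect_equal(effectiveGenotype("+", "-", "F", xLinked = FALSE), "WT")
  expect_equal(effectiveGenotype("-", "-", "M", xLinked = FALSE), "KO")
  expect_error(effectiveGenotype(NA, "+", "F", xLinked = TRUE),
               "maternal allele")
})

test_that("assignEffectiveGenotype fills the column row-wise", {
  df <- data.frame(maternal_allele = c("+", "-", "-"),
                   paternal_allele = c("-", "+", "-"),
                   sex = c("F", "F", "F"))
  out <- assignEffectiveGenotype(df, xLinked = TRUE, context = "placental")
  expect_equal(out$effective_genotype, c("WT", "KO", "KO"))
})

test_that("exact permutation p-values match hand enumeration", {
  # one litter, 3 KO occupying the top 3 ranks: p = 1/C(6,3) = 0.05
  d <- data.frame(litter_id = "L1", weight = 1:6,
                  effective_genotype = rep(c("WT", "KO"), each = 3))
  r <- litterRankPermutationTest(d, alternative = "ko_heavier")
  expect_equal(r@method, "exact")
  expect_equal(pvalue(r), 1 / 20)
  # two litters of 1 WT / 1 KO with KO heavier in both: p = 1/4
  d2 <- data.frame(litter_id = rep(c("A", "B"), each = 2),
                   weight = c(1, 2, 1, 2),
                   effective_genotype = rep(c("WT", "KO"), 2))
  expect_equal(pvalue(litterRankPermutationTest(d2,
                                                alternative = "ko_heavier")),
               0.25)
  # all weights identical: every permuted statistic ties, p = 1
  d3 <- data.frame(litter_id = "L1", weight = rep(1, 6),
                   effective_genotype = rep(c("WT", "KO"), 3))
  expect_equal(pvalue(litterRankPermutationTest(d3,
                                                alternative = "ko_heavier")), 1)
})

test_that("exact convolution agrees with full product-space enumeration", {
  set.seed(11)
  configs <- list(list(sizes = c(6), kos = c(3)),
                  list(sizes = c(4, 4), kos = c(2, 1)),
                  list(sizes = c(5, 3), kos = c(2, 2)),
                  list(sizes = c(3, 3, 4), kos = c(1, 2, 2)))
  for (cfg in configs) {
    recs <- do.call(rbind, lapply(seq_along(cfg$sizes), function(i) {
      n <- cfg$sizes[i]; k <- cfg$kos[i]
      data.frame(litter_id = paste0("L", i),
                 weight = round(runif(n), 3),
                 effective_genotype = sample(c(rep("KO", k),
                                               rep("WT", n - k))))
    }))
    for (alt in c("ko_heavier", "ko_lighter")) {
      r <- litterRankPermutationTest(recs, alternative = alt, exact = "on")
      litters <- split(recs, recs$litter_id)
      ranksList <- lapply(litters, function(l) rank(l$weight))
      koList <- lapply(litters, function(l)
        which(l$effective_genotype == "KO"))
      expect_equal(pvalue(r), oracleLitterExactP(ranksList, koList, alt))
    }
  }
})

test_that("Monte-Carlo p converges to the exact p", {
  set.seed(5)
  recs <- simLitterWeights(nLitters = 3, litterSizes = 6, effect = 0.015,
                           seed = 9)
  ex <- pvalue(litterRankPermutationTest(recs, alternative = "ko_heavier",
                                         exact = "on"))
  mc <- pvalue(litterRankPermutationTest(recs, alternative = "ko_heavier",
                                         exact = "off", nIter = 2000,
                                         seed = 17))
  expect_lt(abs(mc - ex), 3 * sqrt(ex * (1 - ex) / 2000) + 1e-9)
})

test_that("the statistic only depends on ranks (monotone invariance)", {
  recs <- simLitterWeights(nLitters = 2, litterSizes = 6, effect = 0.01,
                           seed = 4)
  r1 <- litterRankPermutationTest(recs, alternative = "ko_heavier",
                                  exact = "on")
  recs2 <- recs; recs2$weight <- exp(recs2$weight * 50)
  r2 <- litterRankPermutationTest(recs2, alternative = "ko_heavier",
                                  exact = "on")
  expect_equal(pvalue(r1), pvalue(r2))
  expect_equal(r1@observed, r2@observed)
})

test_that("single-genotype litters are dropped with a warning", {
  recs <- rbind(
    data.frame(litter_id = "L1", weight = 1:4,
               effective_genotype = c("WT", "WT", "KO", "KO")),
    data.frame(litter_id = "L2", weight = 1:3,
               effective_genotype = "WT"))
  expect_warning(r <- litterRankPermutationTest(recs,
                                                alternative = "ko_heavier"),
                 "L2")
  expect_equal(r@littersDropped, "L2")
  onlyOne <- data.frame(litter_id = "L1", weight = 1:3,
                        effective_genotype = "KO")
  expect_warning(expect_error(
    litterRankPermutationTest(onlyOne, alternative = "ko_heavier"),
    "both genotypes"))
})

test_that("within-litter normalization matches hand arithmetic exactly", {
  recs <- data.frame(litter_id = "L1", weight = c(0.8, 1.0, 1.2, 1.4),
                     effective_genotype = c("WT", "WT", "KO", "KO"))
  out <- normalizeWithinLitter(recs, minPerGenotype = 2)
  expect_equal(out$normalized_weight,
               c(0.8, 1.0, 1.2, 1.4) / 1.1, tolerance = 1e-12)
  # identity: per litter, (mean norm WT + mean norm KO)/2 = 1 exactly
  big <- simLitterWeights(nLitters = 5, litterSizes = 8, effect = 0.02,
                          seed = 21)
  norm <- normalizeWithinLitter(big, minPerGenotype = 3)
  for (l in split(norm, norm$litter_id)) {
    m <- (mean(l$normalized_weight[l$effective_genotype == "WT"]) +
          mean(l$normalized_weight[l$effective_genotype == "KO"])) / 2
    expect_identical(all.equal(m, 1, tolerance = 1e-15), TRUE)
  }
  # all-equal weights normalize to 1
  eq <- data.frame(litter_id = "L1", weight = rep(0.5, 6),
                   effective_genotype = rep(c("WT", "KO"), 3))
  expect_equal(normalizeWithinLitter(eq, minPerGenotype = 3)$normalized_weight,
               rep(1, 6))
})

test_that("litters below the per-genotype minimum are excluded", {
  recs <- rbind(
    data.frame(litter_id = "L1", weight = rnorm(8, 1, 0.05),
               effective_genotype = rep(c("WT", "KO"), 4)),
    data.frame(litter_id = "L2", weight = rnorm(4, 1, 0.05),
               effective_genotype = c("WT", "WT", "WT", "KO")))
  expect_message(out <- normalizeWithinLitter(recs, minPerGenotype = 3),
                 "L2")
  expect_false("L2" %in% out$litter_id)
  expect_error(normalizeWithinLitter(recs[recs$litter_id == "L2", ],
                                     minPerGenotype = 3), "no litter")
})

test_that("placental efficiency is the embryo/placenta ratio", {
  emb <- data.frame(specimen_id = c("a", "b"), weight = c(1.0, 1.2))
  pla <- data.frame(specimen_id = c("b", "a"), weight = c(1.2, 0.1))
  eff <- placentalEfficiency(emb, pla)
  expect_equal(unname(eff["a"]), 10)
  expect_equal(unname(eff["b"]), 1)
  expect_error(placentalEfficiency(emb,
                                   data.frame(specimen_id = "c", weight = 1)),
               "same specimens")
})

test_that("rankSumCompare matches enumeration and handles ties", {
  expect_equal(rankSumCompare(c(1, 2, 3), c(10, 11, 12))$p.value, 0.1)
  expect_equal(rankSumCompare(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  # agreement with wilcox.test exact p for untied small samples
  set.seed(8)
  for (i in 1:10) {
    a <- sample(100, sample(2:4, 1))
    b <- sample(200:300, sample(2:4, 1))
    ours <- rankSumCompare(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
  expect_error(rankSumCompare(numeric(0), 1:3), "non-empty")
})
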