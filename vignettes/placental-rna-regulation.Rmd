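---
title: "Methods: statistics for placental RNA regulation"
author: "trophoRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics for placental RNA regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophoRNA)
```

# Scope

trophoRNA implements the bespoke statistics needed to study how an
RNA-binding protein family (the muscleblind-like, MBNL, proteins — and in
particular the X-linked, placentally imprinted *Mbnl3*) specializes in the
eutherian placenta. Six analysis layers are covered: in vitro
binding-preference summaries, competing splice-donor usage,
litter-structured weight statistics, alternative polyadenylation,
percent-spliced-in (PSI) exon calls, and a tissue-enrichment screen.
Upstream quantification engines (aligners, transcript quantifiers,
differential-usage model fitters) are out of scope: the package consumes
their tabular outputs.

Every layer has a paired synthetic-data generator that plants a known
effect, so each statistic can be validated by parameter recovery rather
than by fixtures copied from any particular dataset.

# Binding-preference statistics from 7-mer Z-scores

RNAcompete-style assays summarize a protein's RNA-binding preference as a
one-sided Z-score per RNA 7-mer — a unitless proxy for relative affinity.
The package computes four summaries over the top-$n$ (default $n = 100$)
7-mers ranked by Z:

* **Motif contribution.** For a motif set $M$,
  $\mathrm{contrib}(M) = \sum_{k \in \mathrm{top}_n,\, k \supset M} Z_k
  \big/ \sum_{k \in \mathrm{top}_n} Z_k$, where $k \supset M$ means the
  kmer contains some motif of $M$ as a literal substring. This measures
  what share of the protein's accumulated top-end affinity a motif family
  explains (e.g. GCUU versus GCAGC preferences across MBNL orthologs).
* **Top Z-score** — the overall strength of the strongest preference.
* **GC-following-base partition.** Among top-$n$ kmers containing a GC
  dinucleotide followed by a base, the summed Z is split by that base
  (GCA/GCC/GCG/GCU) and normalized to 1.
* **GC-spacing log-ratio** —
  $\log_2(\sum Z_{\mathrm{GCxGC}} / \sum Z_{\mathrm{GCxxGC}})$, comparing
  1-bp versus 2-bp spacers between two GC dinucleotides.

Numerical and interpretation choices:

* Ties at the top-$n$ boundary are broken lexicographically on the kmer,
  making the selection deterministic and independent of input order.
* The partition defaults to kmers with *exactly one* eligible GC
  (`singleGC = TRUE`), which makes the following-base classification
  unambiguous; the any-GC reading is available as a flag, in which case a
  kmer's Z counts once per distinct following base. Kmers whose only GC
  occupies the final two positions have no following base and are
  excluded.
* Negative-Z kmers are *retained* when ranking the top-$n$. In practice
  the top 100 of a 16,384-row table is far from the negative tail, so the
  statistics are insensitive to this choice except on tiny tables, where
  the fraction would be ill-defined anyway; a non-positive top-$n$ Z sum
  is reported as an error, and an absent spacing class as a flagged `NA`
  rather than a silent zero.
* Tables arriving in the DNA alphabet are converted (T to U) at load, and
  rows with missing Z are dropped with a reported count.

# Splice-donor (TSS proxy) usage

Competing 5' splice donors that all join one shared reference acceptor
are a read-level proxy for transcription-start-site usage when the TSSs
differ in their first exon. Donors carry an evolutionary class label
(ancestral long-isoform, ancestral exon-skipping, eutherian-specific,
lineage-specific). `donorClassPercent()` reports, per sample group, the
percentage of junction reads per class.

The default aggregation pools counts across a group's samples before
taking percentages, which is robust to low-coverage samples; a per-sample
mean mode is provided, and the two coincide when sample totals are equal.
A zero-count group yields `NA` with a warning, never a silent 0.
Coordinates are 1-based and chromosome-qualified.

# Litter-aware weight statistics

Placenta and embryo weights vary strongly between pregnancies, so the
litter is the exchangeable unit.

**Effective genotype.** *Mbnl3* is X-linked and the paternal X is
silenced in mouse trophoblast, so a heterozygous female's effective
placental genotype follows her maternal allele: WT maternal allele means
effectively WT; a KO maternal allele over a WT paternal allele is a
placental-context KO but unresolvable constitutively. Hemizygous males
follow the maternal allele; autosomal-paralog (Mbnl2-like) heterozygotes
count as WT.

**Rank permutation test.** Weights are ranked ascending within each
litter (mid-ranks for ties, which keeps the statistic exchangeable under
label permutation); the statistic is the summed KO rank across litters.
Genotype labels are permuted independently within each litter, preserving
per-litter genotype counts, and the one-sided p-value is the fraction of
permutations at least as extreme in the stated direction — the direction
is always explicit (`ko_heavier`/`ko_lighter`), never inferred from the
data. The default estimate is `count / n_iter`; the smoothed
`(count+1)/(n_iter+1)` variant and the option to count the observed
labeling as one iteration are exposed as flags, since both conventions
are in circulation. When the number of distinct labelings is at most
$10^6$ the test enumerates instead of sampling: litters are independent,
so each litter's KO rank-sum distribution is enumerated with `combn()`
and the distributions convolved — equivalent to walking the full product
space at a fraction of the cost. Single-genotype litters carry no
contrast and are dropped with a warning.

**Within-litter normalization** divides each weight by the average of the
litter's mean WT and mean KO weight. This gives the exact identity
(mean normalized WT + mean normalized KO)/2 = 1 per litter, so
between-litter baselines cancel while the genotype contrast survives.
The per-genotype minimum defaults to 3 (the calorie-restriction
workflow's rule) and is configurable for designs that pool smaller
litters. Normalized groups are compared with a two-sided Wilcoxon
rank-sum test, exact by enumeration for combined $n \le 20$ (mid-ranks,
so ties are handled exactly) and normal-approximated with tie correction
beyond that. **Placental efficiency** is embryo weight over placenta
weight.

# Alternative polyadenylation from 3'-seq

Reverse-primed 3'-seq reads run antisense to the mRNA, so the cleavage
position is the alignment's 5' end and the mRNA strand is the inverse of
the alignment strand. Sites are called by greedy peak clustering per
chromosome and strand: repeatedly take the position with maximal read
support, absorb all reads within ±50 nt (configurable), emit the site at
the peak. This yields a deterministic partition of reads into sites that
are pairwise more than one tolerance apart; coordinate ties prefer the
smaller position.

**Internal-priming filter.** Oligo-dT can prime on genomic A-rich tracts,
producing spurious sites. A site is kept iff a polyA-signal hexamer
(default AATAAA/ATTAAA, mRNA sense) occurs 10–40 nt upstream, *or* the
20 nt downstream are not A-rich (no run of ≥6 A and fewer than 12 A
total). The hexamer set, windows and A thresholds are this package's
documented defaults — standard practice for 3'-end data — and all are
configurable; removed sites are logged with the reason.

**Pair testing.** Per gene, the proximal/distal pair is tested per
KO-vs-WT comparison on a 2×2 table (site × condition, replicates summed)
with Fisher's exact test and Benjamini–Hochberg correction across pairs
within each comparison. The deliberate design choice here is to *not*
re-implement a generalized-linear differential-usage model: the
significance engine is pluggable (`fdrTable`), so externally computed
per-pair FDRs can drive the same labelling rules. The effect size is the
log2 fold change of proximal *usage*, so scaling both sites equally gives
exactly 0. A pair is `enhanced` (proximal up in KO) or `repressed` only
when the two sites' usage changes oppose each other and FDR < 0.1;
zero cells get a 0.5 continuity correction for the estimate and a
`degenerate` flag.

**Representative pair per gene.** Among the pairs significant in the most
comparisons: (i) take the largest-|FC| candidate if it has ≥15% of the
reads of the gene's best-covered pair; (ii) else fall back to the
best-covered pair; (iii) else, a largest-|FC| candidate with >30% of the
maximum reads; (iv) else discard. With an unconditional step (ii),
steps (iii)/(iv) are unreachable at the default thresholds; the rule is
commonly stated with this ambiguity, so the implementation fixes the
trace shown above, records the decision path per gene, and exposes
`maxReadFallback = FALSE` to disable step (ii) for workflows in which
selection is allowed to fail.

# Differential and developmental splicing

PSI tables carry 0–100 inclusion values and an ordinal per-sample
coverage score (N < VLOW < LOW < OK < SOK). `coverageFilter()` keeps
events at LOW or better in *every* sample by default; unknown labels are
a hard error rather than being silently mapped.

An exon is differentially spliced when the mean KO−WT ΔPSI is ≥15 *and*
every replicate-level difference is ≥5 in the same direction. "Every
replicate-level difference" is read as all KO×WT pairs (equivalently,
min(KO) − max(WT) ≥ 5), the stricter, pairing-free interpretation; an
index-paired mode is provided for designs with genuinely paired
replicates, and the all-pairs call set is provably a subset of the
index-paired one. The same rules define developmental exons between WT
stages. `maturationShiftSummary()` then reports the median KO shift among
developmentally up- and down-regulated exons and the fraction of events
whose KO shift opposes the developmental direction (zero shifts count as
non-opposing) — an anti-maturation signature. ESC-differential reference
sets are accepted through the same interface but are not derived here.

# Expression screen

Enrichment uses two-step averaging: per gene, first the mean TPM of each
tissue group, then `log2((target + eps) / (mean of other group means +
eps))` with `eps = 0.01` TPM guarding zero denominators (the target side
is additionally protected by the TPM > 10 floor, which is applied to the
target *group mean*, not to individual samples). Averaging group means
rather than samples keeps heavily sequenced tissues from dominating the
reference. The paralog-specificity classifier selects genes significant
(padj < 0.05) in the required comparisons and not in the excluded one;
the relaxed candidate rule (raw p < 0.1, |log2FC| > 0.1, both strict) is
intended only for under-powered comparisons.

# Synthetic data: what it emulates, and what it does not

Generator defaults are fixed study-like conditions, not tuning knobs:

* **Kmer tables** plant additive motif bonuses plus Gaussian noise on all
  16,384 7-mers. Real assays have correlated probe effects; planted
  tables have independent noise, so recovery tests demonstrate
  correctness of the statistics, not assay-level robustness.
* **Junction counts** are multinomial draws at a configured depth
  (10,000 by default, giving ±2-point binomial recovery).
* **Litter weights** are litter baseline (0.10 ± 0.015 g) + genotype
  effect + residual noise (0.012 g), balanced litters of 8, six litters —
  E18.5-placenta-like scales. Non-positive weights are truncated at
  1 mg rather than redrawn so litter sizes are preserved. Real litters
  have unequal sizes and sexes; the generator accepts per-litter sizes
  and KO counts but defaults to the balanced design.
* **3'-seq reads** use one synthetic chromosome per gene (keeping FASTA
  small and coordinates trivial), two true sites 400 nt apart with
  AATAAA signals 21 nt upstream, Gaussian jitter (sd 5 nt), and an
  A₁₈ decoy tract with a scrubbed, signal-free upstream window at which
  an `ipRate` fraction of reads is placed. Background sequence is
  generated free of signal hexamers and A-runs so the decoy is the only
  internal-priming feature. Real libraries have heteroscedastic cleavage
  and many-site genes; those are not emulated.
* **PSI tables** plant |ΔPSI| = 20 on 50 of 250 events with per-sample
  noise sd 3 and coverage scores drawn over {LOW, OK, SOK} (tables are
  modelled post-coverage-filter; set the N/VLOW probabilities to exercise
  the filter itself). Baselines are kept in [25, 65] so planted shifts
  cannot clip at the PSI bounds.
* **Expression matrices** plant an 8-fold target-group enrichment on 7 of
  197 genes (a splicing-factor-panel-sized problem) over log-normal
  baselines.

# Validation problem sizes

The test suite and the acceptance script validate, at these sizes chosen
to give tight Monte-Carlo bounds while staying desk-scale: oracle
equivalence of the motif statistics on 1,000 random tables of up to
1,000 rows; Monte-Carlo-versus-enumeration agreement of the permutation
test over eight litter configurations (within $3\sqrt{p(1-p)/1000}$);
type-I error over 500 null simulations (expected in [0.03, 0.07] at
α = 0.05 — slightly conservative because the rank-sum statistic is
discrete); power over 200 simulations at a 3σ effect; polyA recovery at
depth 1,000/condition with jitter sd 5 and 20% internal priming (site
positions within ±5 nt, ≥95% decoy removal, planted 10%→90% shifts
called enhanced at FDR < 0.1); ΔPSI recovery pooled over four simulated
datasets (recall and precision ≥90%); and the exact within-litter
normalization identity.

# Known limitations

* The 2×2 Fisher test treats replicates as exchangeable counts; it does
  not model replicate-level overdispersion the way a GLM-based
  differential-usage engine does. Supply external FDRs for that.
* The permutation test conditions on per-litter genotype counts; it does
  not model litter size as a covariate (by design: the litter is treated
  purely as the exchangeable unit).
* The internal-priming filter is sequence-heuristic; sites inside genuine
  A-rich 3' UTR ends that lack a canonical signal will be discarded.
* The enrichment screen ranks genes; it attaches no significance to the
  log2 fold changes.
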