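---
title: "Methods: classifying and summarizing the pharmacogene variant landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and summarizing the pharmacogene variant landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxlandscape)
```

## The problem

Genes involved in drug absorption, metabolism, transport and response —
ABC and SLC transporters, phase 1 and phase 2 enzymes, nuclear receptors —
carry variation that shapes inter-individual differences in drug response.
Large sequencing cohorts report this variation as per-variant allele
frequencies (VAFs) rather than individual genotypes, so a landscape
analysis works at the summary level: classify each variant by rarity and
predicted function, aggregate per gene and per gene family, and compare
frequencies of clinically relevant variants across populations.
`pgxlandscape` implements that pipeline end to end, together with a
synthetic cohort generator carrying known ground truth so every stage can
be validated without access to restricted cohort data.

## The classification cascade

Each annotated, bi-allelic variant record passes through four rules, in
order:

1. **Quality.** Variants with a Phred-scaled VQSR score below the
   threshold (default 35) are removed. Records with no score pass and are
   tallied separately, because summary-level releases often omit
   per-variant scores; dropping them would empty real inputs.
2. **Rarity.** `RARE` iff VAF < 1%, otherwise `COMMON`. The defining
   inequalities ("less than 1%" rare, "more than 1%" common) leave exactly
   1% unassigned; we close the boundary on the common side so that the
   rare class matches the strict inequality.
3. **Missense consensus.** A missense variant is `DELETERIOUS_MISSENSE`
   when at least half of its *available* predictor calls (SIFT, PolyPhen2,
   PROVEAN) are damaging, `NEUTRAL_MISSENSE` otherwise, and
   `UNCLASSIFIED_MISSENSE` when all three calls are missing. Using the
   available-call denominator rather than a fixed 3 is a design choice:
   with one damaging call out of one available, a fixed denominator would
   call 1/3 and declare the variant neutral on no contrary evidence.
   Unclassified variants are excluded from both the deleterious and the
   neutral tallies. When annotation sources supply raw scores instead of
   calls, they are dichotomised at each tool's published default cutoff
   (SIFT < 0.05, PolyPhen2 ≥ 0.446, PROVEAN ≤ −2.5).
4. **Loss of function.** Splice acceptor, splice donor, start lost and
   stop gained are putatively `LOF`. An optional CADD PHRED threshold can
   demote splice variants scoring below it; the default leaves the filter
   off, since in the motivating cohort CADD judged every splice variant
   deleterious and no numeric cutoff was reported. When enabled, 20 is the
   conventional default.

A variant is *functional* iff it is deleterious missense or LoF. All other
consequences (intronic, upstream, downstream, UTR, synonymous) are
`NON_FUNCTIONAL`, which makes the five classes a partition — a property
the tests assert on every randomized run.

## Summaries

**Per gene** we count each consequence category, novel records (no
external identifier — a `.` in the VCF ID column), rare records, and the
functional partition, and compute the *aggregated functional-variant
frequency*: the sum of the VAFs of the gene's functional variants,
reported in percent. The sum is additive by construction — adding a
functional variant with frequency $v$ raises the statistic by exactly
$100v$ — and can exceed 100% when several common functional variants
co-occur in one gene; a probabilistic alternative,
$1 - \prod_i (1 - v_i)$ (the chance that a random haplotype carries at
least one functional allele under independence), is available as
`summarize_genes(freq_aggregation = "union")`. The rare/common split of a
gene's functional variation is computed by variant count by default, with
a frequency-weighted option (`fraction_weighting = "vaf"`). Genes with no
functional variants report frequency 0 and an *undefined* (NA) rare
fraction, never 0.

**Per family** we aggregate per-gene functional counts into a mean and a
sample (n−1) standard deviation (undefined for single-gene families), and
tally deleterious missense variants and the percentage of them that are
rare.

**Cohort-wide** we report the novel, rare and exonic fractions. "Exonic"
includes UTR variants alongside missense, synonymous and the four LoF
categories — a convention that matches how such cohorts are usually
reported even though UTRs are non-coding. All reported percentages are
rounded half-up to one decimal (`round_pct()`), and the rounding is
applied only at the report layer; full-precision fractions are retained
internally. The substitution spectrum counts the twelve ordered
single-nucleotide substitution types over SNVs only (indels are tallied
separately) and reports the transition/transversion ratio, with an
infinite sentinel when no transversions are observed.

## Statistics

- **Kruskal–Wallis** across families on per-gene counts, tie-corrected,
  chi-square approximation with (groups − 1) degrees of freedom. When
  every observation is tied there is no rank variation and H is 0 by
  convention.
- **Length regressions.** Within each family, ordinary least squares of
  per-gene total, missense and deleterious-missense counts on gene length
  (kb), a two-sided t-test of zero slope, and a Bonferroni threshold of
  0.05/18 (six families × three responses). A constant response returns
  slope 0 and $R^2 = 0$ rather than an error.
- **Population comparison.** Allele counts are reconstructed from each
  population's VAF and total allele number by half-up rounding; the 2×2
  table is tested by Pearson chi-square without continuity correction, or
  by the two-sided Fisher exact test when any expected cell count is
  below 5 (the conventional reading of "Fisher's exact test when
  needed"). The Yates correction is available as a switch but off by
  default. A degenerate table — an allele absent in both populations —
  returns p = 1 with a flag instead of raising. The Bonferroni threshold
  defaults to 0.05/72 in the eight-variant × nine-population design.

The packaged table of eight clinically relevant variants carries
published per-population frequencies, but per-population *allele numbers*
for the non-reference populations are plausible synthetic stand-ins (the
source reports only frequencies), so significance calls on that fixture
illustrate the machinery rather than reproduce the original annotations.

## The synthetic cohort generator

`sim_config()` fixes the study conditions: a 125-gene panel
(16 ABC / 50 SLC / 17 phase 1 / 26 phase 2 / 9 nuclear receptor /
7 other), log-normal gene lengths (meanlog log 40 kb, sdlog 0.8), Poisson
variant counts at 5.5 variants/kb (≈38,000 variants cohort-wide), a rare
fraction target of 0.374, a novel-identifier probability of 0.027, a
consequence mix that is ~93.3% non-coding with the exonic remainder split
~41.6% missense / 31.3% UTR / 25% synonymous and a ~2% LoF sliver, a
transition probability of 0.67 (Ti/Tv ≈ 2, matching a post-filter call
set), a latent missense deleteriousness probability of 0.58, per-tool
predictor accuracy 0.95 with 5% missingness, and VQSR scores ~N(60, 10)
so that ~0.6% of records fall below the threshold of 35. VAFs follow a
two-bin mixture: rare variants uniform on [1/N, 1%), common uniform on
[1%, 50%], with N the cohort allele count (282,862). The mixture is
deliberately not a coalescent site-frequency spectrum — the tests need a
controllable rare fraction, not population-genetic realism — and a
Beta-spectrum option exists for stress tests. Population tables follow
the Balding–Nichols model: given ancestral frequency $p$ and divergence
$F$, each population draws
$p_k \sim \mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$,
converted to counts and back to frequencies; `estimate_fst()` implements
a Hudson-style ratio-of-means estimator used to verify recovery of the
generating $F$.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure, transcript-level annotation ambiguity, correlated
predictor errors (each tool errs independently here, which makes the
consensus slightly better behaved than on real data), mutational
hotspots, and ethnicity substructure within the cohort. Passing tests
therefore demonstrate correctness of the pipeline's logic and
calibration under its stated model, not performance on real cohort data.

A separate truth table records every latent state; it is written next to
the other artifacts but never read by any pipeline stage, which the tests
check explicitly.

## Numerical and degenerate-input choices

- Half-up rounding uses a $10^{-9}$ epsilon to absorb binary
  representation error in ratios whose decimal expansion is exact
  (e.g. 36/40).
- One integer seed drives named substreams (panel, variants, populations)
  so each artifact is independently reproducible; identical configuration
  yields byte-identical files.
- Annotation joins use the key (chrom, pos, ref, alt) after uppercasing
  and left-trimming shared allele prefixes; no other normalization and no
  liftover.
- Multi-allelic VCF rows split into one record per ALT allele;
  conservation of record counts is tested.
- The report manifest omits wall-clock timestamps by default so reruns
  are byte-identical; `write_report(timestamp = TRUE)` opts in.
- Empty cohorts produce header-only tables, zero percentages and a
  manifest flag rather than errors; the fold statistic requires at least
  two genes with positive aggregated frequency and excludes exact zeros
  from the minimum.

## Problem sizes used in validation

The test suite exercises full-scale synthetic cohorts (~38,000 variants,
125 genes) for calibration checks — the rare fraction against its 0.374
target within 99% binomial bounds, deleterious-missense
sensitivity/specificity ≥ 0.85 against the latent truth — and smaller
ten-gene cohorts for invariant and round-trip checks. Oracle-equivalence
tests enumerate all 27 predictor-call triples, all 2×2 tables with total
≤ 40 against exhaustive hypergeometric enumeration, and randomized
Kruskal–Wallis cases against direct rank-sum arithmetic. The type-I error
of the population comparison is measured on 2,000 null replicates at
2,000 alleles per population.

## A worked example

The package ships a 20-variant, two-gene demonstration cohort with hand
countable expectations:

```{r demo}
demo <- system.file("extdata", "demo", package = "pgxlandscape")
bundle <- run_landscape(list(inputs = list(
  vcf = file.path(demo, "demo.vcf"),
  annotations = file.path(demo, "demo_annotations.tsv"),
  panel = file.path(demo, "demo_panel.tsv"))))
bundle$overview[c("n_total", "rare_pct", "exonic_pct", "novel_pct")]
bundle$gene_summaries[, c("symbol", "n_total", "n_functional",
                          "n_functional_rare",
                          "aggregated_functional_freq_pct")]
```

Ten of the twenty variants are functional (six deleterious-consensus
missense, four LoF), seven of those are rare, and the cohort rare
fraction is 7/20 = 35.0%.

## Known limitations

Star-allele/haplotype inference is out of scope, as are the predictor
algorithms themselves (calls or scores are ingested, not computed), dbSNP
lookups, VEP execution and liftover. Reproducing the original cohort's
absolute counts is impossible from public material — the underlying
genotype-level data are not downloadable — so validation rests on the
published ratios among published counts, oracle equivalence of the
statistical primitives, and calibration on synthetic data.
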