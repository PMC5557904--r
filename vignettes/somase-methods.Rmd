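---
title: "Methods: allele-specific expression of somatic variants from matched DNA/RNA counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific expression of somatic variants from matched DNA/RNA counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somase)
```

## The problem

A somatic point mutation sits on one chromosome of a (locally) diploid tumor
genome. If transcription treated both alleles equally, the variant allele
fraction observed in tumor RNA would mirror the fraction observed in tumor
DNA. Departures from that expectation — the variant allele dominating the
transcriptome, or vanishing from it — are informative: they can reflect
cis-regulatory effects of the mutation itself, surveillance pathways such as
nonsense-mediated decay, or selection on the mutant protein. `somase`
quantifies these departures per site and classifies the extremes.

The pipeline consumes, for every candidate site in every patient, the
variant/reference read counts from four matched sequencing datasets: normal
exome, normal transcriptome, tumor exome, tumor transcriptome. It does not
align reads or call variants; upstream tools produce the count table.

## Core quantities

For a dataset with `n(ref)` reference and `n(var)` variant reads at a site,

- **VAF** = `n(var) / (n(ref) + n(var))`, computed separately per dataset
  ([vaf()]).
- **V_RD** = `VAF(tumor RNA) / VAF(tumor DNA)` ([v_rd()]): 1 when RNA mirrors
  DNA, above 1 when the variant allele is over-represented in the
  transcriptome, below 1 when under-represented. Because it conditions on the
  tumor-DNA VAF, V_RD absorbs sample-level composition effects — tumor
  purity, residual structural variation — that depress both VAFs together.
  V_RD is a single scalar (the quotient) and is not capped above 1, so it can
  be correlated against scalar annotation scores.

## The exclusion ledger

Allelic imbalance at a point mutation is only attributable to the mutation if
nothing else distorts the allele ratio. `apply_filters()` therefore removes,
per (sample, site):

1. **Coverage** — tumor DNA or tumor RNA depth below 10 reads. The boundary
   is inclusive: exactly 10 reads passes, since the rule excludes strictly
   "fewer than 10".
2. **Imprinted regions** — parent-of-origin mono-allelic expression would
   mimic an expression extreme. Any user-supplied BED of imprinted regions is
   accepted; the package ships none and claims no authoritative list.
3. **Copy-number alterations** — per-sample SEG segments with
   `|seg_mean| > 0.1`. The 0.1 default is the conventional SNP-array cutoff
   for calling a segment non-neutral; it is a package choice (the source
   material does not define "affected") and is exposed in `filter_config()`.
4. **Germline signal** — more than `germline_max_var_reads` (default 1)
   variant reads in normal DNA or normal RNA. A strict zero would discard
   true somatic sites at high normal depth on a single error read, so one
   stray read is tolerated; the threshold is configurable down to 0.
5. **Bi-allelic tumor DNA** — `0 < VAF(tDNA) < 1`, so RNA imbalance cannot be
   explained by genomic loss of an allele.

Cohort assembly additionally excludes **hypermutator samples**: mutation
count above the cohort mean plus 3 sample standard deviations
(`exclude_hypermutators()`, n−1 denominator — it is a sample statistic over
the cohort).

All filters are pure predicates; the retained set is order-independent.

## The caller

For each retained site the tumor-RNA variant count `k` out of depth `n` is
tested against an exact binomial null ([exact_binomial_p()]):

- `null_mode = "dna_matched"` (default): `p0 = VAF(tDNA)` of the same site,
  so the test asks whether RNA departs from the sample's own genomic allele
  composition — the same rationale as V_RD. This is the package's design
  choice; a `"half"` mode (`p0 = 0.5`) is kept for comparison because the
  exact null of the original count-integration tool is not restated in the
  source material.
- Two-sided p-values use the minimum-likelihood convention: the sum of
  probabilities of all outcomes whose point probability does not exceed that
  of the observed `k`, with a relative tie tolerance of 1e-7 (documented
  because two-sided exact tests are convention-dependent).
- P-values are adjusted per batch (all sites of a run jointly) by the
  Benjamini–Hochberg step-up ([bh_adjust()]).

A site is called **SOM-E** (somatic over-expression) when `q < alpha` *and*
`VAF(tRNA) >= tau_e` (default 0.9), **SOM-L** (somatic loss) when `q < alpha`
and `VAF(tRNA) <= tau_l` (default 0.05), otherwise expressed-balanced.
"Mono-allelic" is a statement about the fraction, not only about
incompatibility with the null — with high depth, a VAF of 0.6 can be wildly
significant yet is not mono-allelic. The thresholds make "~1" and "~0"
numerically concrete (they are not defined in the source material): 0.9
operationalises "essentially only the variant allele is seen", 0.05 "the
variant allele is not expressed beyond stray reads".

## Cohort statistics

- `recurrence_spectrum()` keys mutations by (chrom, pos, ref, alt) — the
  standard variant identity — and histograms how many samples share each.
- `spearman_rho()` ranks with average ties and drops incomplete pairs
  pairwise; missing annotation scores are never imputed.
- `kruskal_wallis()` computes the tie-corrected H with a chi-square
  approximate p (adequate at cohort sizes in the hundreds); a seeded
  permutation p is available for tiny groups.
- `contingency_2x2()` offers the two-sided Fisher exact test (full
  hypergeometric enumeration, minimum-likelihood rule) and a Pearson
  chi-square that applies Yates's continuity correction automatically when
  any observed cell is below 5 ("fewer than 5 measurements in any category"
  is read as any cell < 5).
- `stratified_summary()` groups calls by an annotation key (functional
  class, cancer-gene-list membership, ...), reports per-group V_RD and
  call-class counts, runs Kruskal–Wallis across strata (a Welch t-test
  option exists because mean comparisons are sometimes wanted, but the
  rank test is the default headline test), and tests call-class proportions
  pairwise with joint BH correction.

## The synthetic cohort: what it emulates, what it does not

Real matched tumor/normal exome + transcriptome cohorts are access
controlled, so `generate_cohort()` provides the stated world every test runs
against. Defaults describe a plausible breast-tumor cohort and are fixed,
not tuned: 72 samples × 17 sites (the scale of the motivating cohort), tumor
purity 0.6 (a typical consensus-purity value for such cohorts), 80×/60×
negative-binomial DNA/RNA coverage with size 4 (RNA-seq-like overdispersion;
no per-site coverage distribution is published for the motivating cohort, so
these are stand-ins, not estimates), sequencing error 1e-3, SOM-E/SOM-L
fractions 0.05/0.38 among clean somatic sites (the reported cohort-level
proportions), 5% germline-heterozygote contaminants, 5%/2% of sites planted
inside CNA/imprinted intervals, and a target score correlation of 0.30.

Generative model per site:

- Depths: negative binomial per dataset.
- Tumor DNA: clonal heterozygous diploid, variant count binomial with
  success probability `purity/2`. Subclonal structure and CNA-driven VAF
  shifts are deliberately not modelled: CNA-overlapping sites are excluded
  by design, and clonality is out of scope.
- Tumor RNA: variant fraction `1 − seq_error` for SOM-E truth, `seq_error`
  for SOM-L, and for balanced sites a beta-binomial centred on the site's
  true DNA VAF with intra-class correlation `rna_overdispersion` (default
  0.05 to emulate biological allelic noise; 0 gives exactly binomial counts,
  the null used by the calibration tests).
- Normal tissue: variant reads at the sequencing-error rate (0.5 for
  germline contaminants, which show ~0.5 VAF in all four datasets).
- Intervals: imprinted regions and per-sample CNA segments are generated in
  coordinate bands disjoint from clean sites, so planted sites overlap an
  exclusion interval with probability 1 and clean sites never do. Copy-
  neutral segments (`|seg_mean| < 0.05`) are also planted over clean sites
  to exercise the threshold path.
- Annotation scores: the primary score (`cadd`) is built by a Gaussian
  copula whose latent mixing weight is solved by root finding — with common
  random numbers, so the objective is deterministic and monotone — such that
  the realised Spearman correlation with the true RNA variant fraction on
  the generated cohort equals `score_rho`. Secondary scores share a damped
  latent factor; 8% of secondary score cells are set missing to exercise
  pairwise-complete handling. Because all clean somatic sites share the same
  true DNA VAF, rank correlation against the true RNA fraction equals rank
  correlation against the true V_RD.

One seed drives every draw through a single stream (saved and restored
around generation), so identical configurations give identical cohorts.

A green test on this generator establishes that the pipeline recovers truth
under its own stated world; it does not establish performance on real data,
where coverage is locus-dependent, mutations recur across samples, allelic
noise is gene-specific, and annotation scores correlate with expression for
biological rather than copular reasons. The generator emits all-unique
sites; recurrence behaviour is tested on explicitly constructed tables.

## Numerical choices and degenerate inputs

- Zero-depth VAF is an error, never `NaN`: such sites must have been
  coverage-filtered first.
- `v_rd` requires `0 < VAF(tDNA) < 1`, which the somatic filter enforces.
- BH q-values are returned in input order; the empty batch yields an empty
  call set rather than an error.
- Fisher tables with a degenerate support (single possible table given the
  margins) return p = 1; all-zero tables are an error.
- Coordinates are 1-based inclusive everywhere internally (VCF convention,
  matching the locus notation the analysis targets); BED's 0-based half-open
  convention is converted at the reading boundary and never leaks inward.
- Calls files store reals at 15 significant digits so write/read cycles are
  stable to at least 12 significant digits; integers round-trip exactly.

## Known limitations

- Single-nucleotide substitutions only; indels are rejected at parse time.
- No phasing, no gene-level expression, no NMD mechanism model: SOM-L is a
  description of allele loss, not an explanation.
- The chi-square p for Kruskal–Wallis is approximate; use the permutation
  mode for very small groups.
- The simulator's coverage and contamination defaults are plausible
  stand-ins; conclusions about absolute sensitivity transfer to real data
  only to the extent those defaults match it.
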