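---
title: "Methods: calling and interpreting tissue-culture-induced methylation change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and interpreting tissue-culture-induced methylation change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(methregen)
```

# The problem and the model

Whole-genome bisulfite sequencing reads report each cytosine as methylated
(#C) or unmethylated (#T); the fractional methylation of a site or pooled
region is #C/(#C+#T). Plant genomes methylate cytosines in three sequence
contexts — CG, CHG and CHH (H = A, T or C) — maintained by different
pathways, with CHH methylation guided by 24-nt siRNAs. Tissue culture and
plant regeneration perturb this landscape: regenerated plants lose
methylation at partially shared "susceptible" sites, preferentially in gene
promoters, and the losses are largely heritable; callus instead gains CHH
methylation at promoters, a state erased on regeneration. `methregen`
implements the analysis chain for this phenomenon plus a generative model of
the data for validation.

## The DMR definition

A differentially methylated region is built from 100-bp bins:

1. **Binning.** Counts are pooled per bin over all cytosines of one context
   on both strands, separately for sample and wild-type control. Pooling
   across strands is a deliberate choice (the source protocol does not state
   it): it maximises per-bin counts and matches the scale of the
   10-informative-cytosine eligibility rule in a genome where a 100-bp bin
   holds roughly 9 CG, 7 CHG and 26 CHH sites.
2. **Eligibility.** A bin is tested only when both sides hold at least 10
   informative cytosines (covered by ≥ 4 reads). By default ineligible bins
   are removed *before* testing so they contribute no hypothesis to the
   multiple-testing family (`filter_stage = "pre"`); the literal
   apply-the-filter-last order is available as `filter_stage = "post"`.
   Excluding untestable bins before correction is the statistically cleaner
   reading and, because an ineligible bin can never become a DMR either way,
   the two orders differ only through the BH family size.
3. **Testing.** Each eligible bin's 2×2 table of pooled methylated and
   unmethylated read counts is tested with a two-sided Fisher's exact test
   (implemented in C++ by hypergeometric summation; point probabilities tied
   with the observed one within a relative 1e-7 are included, matching the
   standard convention for the discrete two-sided test). Pooling reads
   within a bin treats them as independent Bernoulli observations — the only
   reading under which a count-based exact test per bin is defined.
4. **Correction and thresholds.** Benjamini–Hochberg adjustment is applied
   per (sample, context) across all eligible bins genome-wide; significance
   requires q < 0.01 *and* an absolute pooled difference of at least 0.7,
   0.5 or 0.1 for CG, CHG, CHH. A difference exactly at the threshold
   passes (≥). The per-context family matches how DMRs are reported;
   whether correction should span contexts jointly is unknowable from the
   protocol and is a one-line change.
5. **Merging.** Significant bins of the same direction (hypo/hyper, by the
   sign of the difference) separated by at most 100 bp are merged; adjacent
   bins always merge. Directions are never merged together — hyper- and
   hypomethylation are reported as separate DMR sets. Pooled levels are
   recomputed over the merged span. Minimum DMR size is therefore one bin.

The non-conversion error rate is estimated per context as the pooled
apparent methylation of the chloroplast, which is naturally unmethylated —
any apparent methylation there is failed bisulfite conversion.

## Comparison, stability, enrichment, expression

* **Overlap matrices** are asymmetric by design: entry (i, j) is the percent
  of sample i's DMRs touching (≥ 1 bp) a DMR of sample j. Common DMRs are
  reported as intervals of the *first* (reference) set because DMRs are
  sample-anchored entities, not genomic intersections.
* **Stability** of a T2 hypomethylation DMR across T4 and T6 uses the
  half-of-wild-type rule on pooled CG levels: "loss" is strictly less than
  half the wild-type level, so exact equality counts as the complementary
  "gain" — a measure-zero event on real data that needs a deterministic
  tie-break. The four categories are (T4, T6) = (loss, loss) stable_loss,
  (gain, gain) recovered_T4, (loss, gain) recovered_T6_only and
  (gain, loss) transient_T4. Pooled fractions (not means of per-site
  fractions) keep the classifier scale-invariant and consistent with the
  caller.
* **Heat maps / clustering** use complete linkage on Euclidean distances;
  rows with any missing (zero-coverage) value are flagged and removed before
  clustering, mirroring the convention of omitting such rows from display.
* **Enrichment** compares the number of DMRs overlapping a feature class
  with 100 randomized sets that preserve the observed number and length
  multiset. Randomized intervals are placed independently and uniformly,
  on a chromosome drawn proportionally to its length (`match_chrom = TRUE`
  restricts each to its source chromosome); they may overlap each other —
  the simplest null preserving number and size. The empirical p uses the
  add-one estimator, so p < 0.01 with 100 sets means the observation beat
  every randomization and p can never be 0.
* **Differential expression** applies fourfold and FDR < 0.01 cutoffs. The
  underlying test is unspecified in the source protocol; we use the
  two-sided Fisher's exact test of each gene's count against the library
  remainder — a standard two-library count test of that era — with BH
  correction over tested genes, exposed behind `call_de()` so the statistic
  is replaceable. Fold changes use +0.5 pseudocounts on library-normalized
  counts to survive zeros on one side; genes with zero counts in both
  samples are excluded entirely and never enter any denominator.
* **Metaprofiles** scale each region to a fixed number of windows with
  *equal-length* flanks on both sides (20/20/20 windows by default; the
  resolution is not specified by the source and any reasonable value
  preserves the qualitative shape). Methylation per window is the pooled
  fraction; density signals are per-bp means with absent positions counting
  as zero. Per-bp data are assigned to windows by fractional overlap, so
  regions shorter than the window count are exact rather than dropped.
  Flanks truncated by a chromosome end are computed on the available span
  and flagged.

# The synthetic world

`sim_config()` states the generative model; its defaults are the conditions
the analysis assumes, chosen once:

* **Genome.** Random sequence at GC 0.43 (rice-like); non-overlapping
  protein-coding genes (2–6 kb, 2–5 exons) and TE genes (1–4 kb) separated
  by ≥ 2.5 kb so each gene has promoter room; a 150-kb "chloroplast" with
  true methylation 0 everywhere. The default unit world is a 1-Mb
  chromosome; tests scale it up or down explicitly.
* **Methylation landscape.** Methylated loci (TE genes ± 500 bp and a
  25% subset of promoters) carry CG/CHG/CHH levels 0.85/0.55/0.07;
  unmethylated loci 0. Gene bodies add a CG-only gradient from 0.2 at the
  TSS to 0.6 at the TTS, emulating the canonical gene-body profile.
* **Planted DMRs.** Hypomethylated regions (defaults: 300–900 bp, CHH
  ≥ 400 bp) are planted half in methylated promoters, half in TE loci, with
  ≥ 300 bp separation so distinct truths cannot merge into one call.
  Placement rejects candidate windows lacking two 100-bp bins with ≥ 10
  context cytosines: real methylated regions (TEs, RdDM islands) are
  context-dense, while uniform random sequence at GC 0.43 averages *below*
  the caller's informative filter for CG and CHG — unconstrained placement
  would plant undetectable truths and break the generator's own
  truth-consistency guarantee.
* **CHH islands.** The stated per-context loss depths (0.8/0.6/0.15) exceed
  the CHH background of 0.07, so planted CHH regions are elevated to
  `chh_island_level = 0.25` (RdDM-target-like); the multiplicative loss
  `p → p(1 − δ/p₀)` then realises exactly the configured absolute drop. For
  CHG the multiplier floors at zero and the realised drop (0.55) still
  clears the caller's 0.5 threshold; this is kept as stated.
* **Sharing and inheritance.** Each regenerant line loses each planted
  region independently with probability 0.5 (`shared_site_fraction`),
  reproducing partial, asymmetric overlap between lines. For the
  multi-generation line, each T2 loss draws an inheritance category with
  probabilities 0.10 (recover in T4, keep in T6), 0.044 (recover only in
  T6), 0.02 (recover in T4, lose again in T6), remainder stably lost — a
  world in which all four stability categories occur.
* **Callus.** CHH methylation +0.2 (capped at 1) at a distinct set of
  otherwise unmethylated promoters, in callus only; regenerants never
  inherit it. Callus hypomethylation is not modelled (observed to be weak
  for pooled calli) — a known simplification.
* **Observation model.** Coverage is Poisson(15) per site; methylated calls
  are Binomial with success `p + (1 − p)·error_rate`, error_rate = 0.012:
  non-conversion only inflates apparent methylation, which is exactly the
  asymmetry the chloroplast-based error estimate measures. Failure to call
  a truly methylated read is set to 0.
* **siRNA and mRNA.** 24-nt read counts per 100-bp window are Poisson with
  rate proportional to the window's summed true CHH methylation
  (per sample), 21-nt reads are a uniform background; mRNA counts are
  negative binomial (mean 200, dispersion 0.05) with the mean multiplied by
  4 in samples where a responsive gene's promoter DMR is lost
  (`responsiveness = 0.3`: only some genes respond).

Everything is a pure function of `(config, seed)`; sub-seeds are derived
from the one seed and kept below 2³¹.

**What a green test does not establish.** The generator draws reads as
independent binomials on independent sites: it has no read-level
autocorrelation, no mappability or GC bias, no partial methylation from
cell-type mixtures, no heterozygous (segregating) losses, and its genome
lacks the repeat structure that makes real alignment hard. Recovery results
on it validate the statistical machinery, not robustness to alignment
artefacts.

# Numerical choices and degenerate inputs

* Fisher tie tolerance 1e-7 (relative) on point probabilities; all-zero or
  zero-margin tables give p = 1 by convention.
* BH: step-up with capping at 1, order-preserving; a single p is returned
  unchanged; empty input gives empty output.
* Fractional methylation of an uncovered site is `NA`, deliberately
  distinct from 0; uncovered regions flag their row rather than silently
  contributing zeros.
* Cytosines within 2 bp of a chromosome end lacking a complete
  trinucleotide default to CHH (negligible count; avoids dropping sites);
  any N in the defining bases makes the site `not_cytosine` and it is
  excluded everywhere.
* Coordinates are 0-based half-open internally; call files are read/written
  1-based; BED output follows BED. Adjacent half-open intervals do not
  overlap (the 1-bp rule needs a true shared base).
* TSS distance ties between equidistant genes break to the smaller gene id.
* `classify_stability` reports zero-coverage regions as `unclassifiable`
  instead of guessing.

# Validation design

The test suite pins the two core statistics to independent oracles
(exhaustive hypergeometric enumeration for every 2×2 table with N ≤ 30;
a brute-force step-up for BH) and then validates each stage by recovery on
the synthetic world: planted-DMR sensitivity and precision at 10 Mb/15×,
zero-DMR null calibration between two count draws of one methylome,
chloroplast error-rate recovery, stability-category fractions against their
generating probabilities, promoter-enrichment flagging against uniform
placement, and metaprofile body/flank differences against the planted
depth. The null calibration runs at 2 Mb × 100 seeds rather than 10 Mb ×
100 for runtime; the controlled quantity (the per-context BH family error)
is bin-level and the smaller genome still tests ~9,000 eligible CG bins per
seed.

One documented limit: with expression effects planted at *exactly* the
fourfold calling cutoff, the observed fold of a truth-DE gene clears the
cutoff only about half the time (the effect sits on the decision boundary;
even the noiseless pseudocounted fold is 3.99), so recall against
boundary-planted truths is ~0.5 rather than high — the corresponding
acceptance check documents this honestly rather than moving either the
effect or the threshold.

# Known limitations

* The DMR caller is the binned exact-test design it re-implements: no
  smoothing, no beta-binomial dispersion, no per-cytosine calls — by scope.
* Fisher's exact test on pooled bins ignores read-to-read overdispersion;
  with biological replicates a dispersion-aware model would be preferable.
* The DE test against library remainders has no replicate dispersion
  either; it is pluggable behind `call_de()`.
* Randomized-interval nulls are not matched for GC, mappability or
  chromosome of origin (a `match_chrom` flag covers the latter).
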