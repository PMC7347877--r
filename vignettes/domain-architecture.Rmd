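---
title: "Quantifying two-condition changes in chromatin architecture and regulatory signal"
author: "domainweaver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying two-condition changes in chromatin architecture and regulatory signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainweaver)
```

## The analysis

domainweaver implements an integrative analysis of processed chromatin data
from two conditions — a control and a knockout — that asks how changes in
genome architecture relate to changes in the regulatory epigenome. The
inputs are the standard products of upstream pipelines: peak intervals
(BED), rpm coverage tracks (bedGraph), contact-domain calls (BED), loop
calls (BEDPE), per-chromosome sparse observed-over-expected (O/E),
KR-normalized Hi-C contact matrices as text triples, gene annotation (GTF),
and stranded RNA fragment intervals. Domain and loop *calling* is
deliberately upstream of this package (Arrowhead/HiCCUPS-style callers);
domainweaver consumes their calls.

The analysis proceeds in stages:

1. **Architecture merging and classification.** Per-condition domain calls
   are merged when both borders lie within 20 kb; loop calls when both
   anchor midpoints lie within 10 kb. A merged domain is a *loop domain*
   when some loop's anchors lie within 25 kb of its two boundaries,
   otherwise *compartmental*; a loop is a *boundary* loop when it matches a
   domain that way, an *intra-domain* loop when both anchors fall strictly
   inside one domain, and *other* otherwise. "Within N kb" is inclusive
   throughout, and the anchor–boundary distance is measured from the
   boundary point to the nearest point of the anchor interval.
2. **Regulatory elements.** Active promoters are TSS positions lying inside
   both a DNaseI and an H3K27ac peak; active enhancers are DNaseI peaks
   with at least 25% reciprocal overlap with an H3K27ac and an H3K4me1
   peak. Each element carries a 1 kb quantification window centered on the
   TSS or DHS midpoint.
3. **Signal quantification.** Track signal is averaged (length-weighted,
   uncovered bases zero, replicates equally weighted) over the 1 kb
   windows; per-domain signal is the unweighted mean over the DHS windows
   whose midpoints fall in the domain. Changes are
   `log2((cko + 0.1) / (ctrl + 0.1))` rpm, and domains are classed
   *increased* (> 0.585), *decreased* (< −0.585) or *unchanged* (strictly
   between; boundary values are unchanged). 0.585 is log2(1.5).
4. **Contact statistics.** Domain contacts are the mean O/E over
   off-diagonal bin pairs fully inside the domain; loop contacts the mean
   over the anchor-bin rectangle; boundary insulation the negative log2
   ratio of boundary-crossing to total contacts in a window of one domain
   length on each side; aggregate peak analysis (APA) averages the
   21 × 21-pixel neighbourhoods of loop centers and scores the center
   against the lower-left 5 × 5 corner box (P2LL). The A/B compartment
   eigenvector is the leading eigenvector of the Pearson correlation matrix
   of 150 kb O/E rows, sign-oriented so that positive bins correlate with
   per-bin H3K27ac; domains take the mean eigenvalue of the 150 kb bins
   they span.
5. **Enhancer RNA.** For each enhancer-overlapping DHS, two 2 kb stranded
   windows flank the peak center (upstream counted on the Crick strand,
   downstream on the Watson strand). A feature is removed when either
   window touches a protein-coding gene or lncRNA body extended 1 kb past
   TSS and TES, fragments are assigned by 5′ end and strand, features with
   fewer than ten total counts are removed, and fold-changes are computed
   after median-of-ratios size-factor normalization with a 0.5 pseudocount.
6. **Distance-controlled resampling.** To compare the contact change at
   loop-domain boundary loops against intra-domain DHS pairs in domains
   with increased accessibility, all within-domain DHS-center pairs are
   enumerated and 100 resampled pair sets are drawn that match the test set
   in size and pairwise-distance histogram; the one-sided empirical p-value
   is the fraction of resampled medians below the test median.

## The synthetic-data generator

Because the full study-scale datasets cannot be regenerated at desk scale,
the package ships a generator (`sim_config()`, `generate_dataset()`) whose
defaults define the study conditions used by the tests and by
`scripts/acceptance.R`:

* three 9 Mb chromosomes at 10 kb matrix resolution, 20 domains each
  (250–450 kb, non-overlapping, three-bin gaps, borders on the bin grid);
* a 20/70/10 increased/unchanged/decreased class mix with planted
  accessibility log2FC drawn per class and rejection-sampled into
  class-consistent bands (increased ≥ 0.75, |unchanged| ≤ 0.45,
  decreased ≤ −0.75) so that classification is exact in the zero-noise
  limit despite the fold-change pseudocount;
* per-domain contact log2FC coupled to the accessibility log2FC with slope
  0.5, with a noise vector orthogonalized in-sample and scaled so that the
  planted Pearson correlation equals the configured target (0.6 by
  default) exactly — this keeps the planted correlation stable across
  seeds at n = 60 domains, where a free noise draw would make the sample
  correlation fluctuate by ±0.1 or more;
* O/E matrices built as a clean structure — background 1.0, domain blocks
  elevated 1.6-fold, loop pixels enriched 3-fold in both conditions — with
  the knockout multiplied by the per-domain fold-changes and each condition
  receiving independent mean-one log-normal pixel noise (sdlog 0.1);
* a 1.2 Mb checkerboard compartment structure planted in separate 150 kb
  matrices (±0.4 around an O/E of 1.0), with the A blocks also receiving a
  small H3K27ac background elevation so the eigenvector can be oriented;
  the compartment structure is planted at block scale, so aggregating the
  10 kb matrices would add nothing;
* five DHS per domain (the first promoter-like, with a gene TSS planted at
  its center; the rest enhancers) with 1 kb signal peaks whose knockout
  height scales with the planted log2FC, plus per-window log-normal signal
  noise (sd 0.15 log2 units);
* negative-binomial stranded eRNA fragments, two replicates per condition,
  mean 60 and size 15. The size was fixed by a design-time power
  calculation: moderate overdispersion typical of concordant biological
  replicates, at which a broad planted fold-change vector is recovered
  with Spearman ≈ 0.94 at these counts. With the default class-mixture
  planted effects the end-to-end Spearman is lower (≈ 0.75), because 70%
  of features carry near-zero planted changes whose ranks are
  noise-dominated — that value is reported, not asserted;
* knockout-condition domain/loop calls are jittered by up to 5 kb so the
  merge step does real work; intra-domain loop anchors sit at least three
  bins apart and four bins inside the boundaries so that jittered,
  merged anchors can never collide on the bin grid or within the 25 kb
  classification tolerance.

Identical configuration (including the seed) reproduces every bundle bit
for bit; the test suite asserts this.

What the generator does *not* emulate: read-level noise, peak-calling
uncertainty, replicate-level Hi-C variation, KR balancing artifacts,
distance-dependent O/E variance, chromosome-scale heterogeneity, or any
systematic difference between boundary-loop and intra-domain contact
changes (the generator is neutral there, so the resampling p-value is
calibrated rather than extreme). Passing tests therefore demonstrate that
the statistics recover planted structure of the assumed form, not that
real data satisfy those assumptions.

## Numerical choices

* The diagonal (i = j) is excluded from domain contacts and insulation
  totals: self-bin signal is not an interaction.
* Absent sparse entries are zeros in all means, consistent with O/E dumps
  that omit empty pixels.
* Insulation uses log base 2 with a 1e−6 stabilizer in numerator and
  denominator; on a uniform matrix the score is `-log2(ell / (2*ell - 1))`,
  which the tests verify for ell = 1..10.
* APA uses a half-width of 10 bins with a `ceiling(w/2)` corner box; loops
  whose window would cross the diagonal or the chromosome edge are skipped
  and counted.
* The leading eigenvector is chosen by the largest absolute eigenvalue;
  orientation fails loudly on zero-variance H3K27ac.
* The fold-change pseudocount is 0.1 rpm for signal (small against the
  ~10 rpm peaks) and 1e−3 O/E units for single-pixel ratios.
* Resampling bins distances in log2-width bins, respecting the
  distance decay of contact frequency; within a resample, draws are
  without replacement, falling back (and counting) when a bin is
  exhausted; the empirical p divides by N so that "1 of 100 below" is
  exactly 0.01, with the conservative (k+1)/(N+1) variant behind a flag.
* Merging is greedy one-to-one nearest-first with ties broken toward the
  smaller start, and midpoint distance is used for loop matching since
  caller output is bin-aligned.
* "1 kb around" a TSS/center is implemented as a 1,000 bp total window
  (±500 bp).
* A whole eRNA feature is dropped when either stranded window overlaps an
  exclusion region; half-features would have incomparable totals under
  the shared count filter.

## Problem sizes

The default generator produces 60 domains, 60 loops, 300 DHS, ~240 eRNA
features, three 900-bin 10 kb matrices and three 60-bin 150 kb matrices
per condition. The test suite additionally exercises an 8-domain
single-chromosome configuration, 1,000-case randomized oracle comparisons
on matrices of up to 50 bins, and a 200-repetition calibration of the
resampling null; these sizes were chosen so the whole suite completes in
about a minute while keeping every estimate's sampling error well inside
the asserted tolerances.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(rng_seed = 7)
ds <- generate_dataset(cfg)
out <- run_pipeline(ds, default_run_config(seed = 7))
out$correlations
summarize_by_class(out$domains, "contacts_log2fc")
out$apa$control
out$resampling
```

The domain table carries per-condition contact means, per-assay signal and
log2FCs, the accessibility class, insulation, and the domain eigenvalue;
the loop table the per-class contact changes; `out$log` accounts for every
record entering each filter.

## Limitations

Statistical testing beyond the resampling null (differential-peak calling,
Kruskal–Wallis/Dunn comparisons, DESeq2 dispersion modelling) is out of
scope and delegated to standard tools. The correlation panel reports
coefficients and two-sided p-values only. Contact matrices are assumed
O/E KR-normalized on input; no balancing is performed. Loop and domain
calls are trusted as given apart from merging and classification.
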