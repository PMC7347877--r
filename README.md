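# domainweaver

Integrative analysis of two-condition (control vs knockout) chromatin
architecture and regulatory-epigenome data: contact-domain and loop
interaction changes on observed-over-expected (O/E), KR-normalized Hi-C
matrices, boundary insulation, A/B compartment eigenvectors, aggregate
peak analysis, regulatory-element classification, per-domain accessibility
fold-change classes, strand-specific enhancer-RNA quantification, and a
distance-controlled resampling null. It is written for analysts who
already have processed files in hand — peaks (BED), rpm coverage
(bedGraph), Arrowhead/HiCCUPS-style domain and loop calls (BED/BEDPE),
juicer-dump-style contact triples, GTF annotation, stranded fragment
intervals — and want the downstream quantification and comparisons done
reproducibly.

## The statistics at the core

For a domain *D* spanning matrix bins *b1..bn* at resolution *r*, the
domain contact strength is the mean O/E value over off-diagonal bin pairs
inside *D*; for a loop with anchor bin sets *A1*, *A2* it is the mean over
the *A1 × A2* rectangle. Changes are `log2((KO + c) / (Ctrl + c))` with a
small pseudocount *c*, and domains are classed increased / unchanged /
decreased at ±0.585 (1.5-fold). Boundary insulation is
`-log2(crossing / total)` contact sums in a window of one domain length on
each side of a boundary. APA averages the (2w+1)² pixel neighbourhoods of
loop centers and reports P2LL, the center value over the mean of the
lower-left corner box. The compartment eigenvector is the leading
eigenvector of the Pearson correlation matrix of 150 kb O/E rows, oriented
so positive values track H3K27ac. The resampling null draws 100 pair sets
of intra-domain DHS pairs matched to a test set (boundary loops of
loop domains with increased accessibility) in number and pairwise-distance
histogram, and reports the one-sided empirical p-value
`(# resampled medians < test median) / 100`.

Every stage can be validated against a built-in synthetic-data generator
with planted effect sizes (domain accessibility and contact fold-changes
with a configurable coupling, loop-pixel enrichment, a compartment
checkerboard, negative-binomial eRNA counts).

## A worked example

```r
library(domainweaver)

cfg <- sim_config(rng_seed = 7)          # 60 domains, planted r = 0.6
ds  <- generate_dataset(cfg)
out <- run_pipeline(ds, default_run_config(seed = 7))

out$correlations
#>                     comparison   method estimate  p.value  n
#> 1    accessibility_vs_contacts  pearson   0.5748 1.56e-06 60
#> 2          h3k27ac_vs_contacts  pearson   0.6182 1.42e-07 60
#> 3             smc1_vs_contacts  pearson   0.5914 6.49e-07 60
#> 4      eigen_delta_vs_contacts spearman  -0.0802 5.42e-01 60
#> 5 eigen_delta_vs_accessibility spearman   0.1369 2.96e-01 60

summarize_by_class(out$domains, "contacts_log2fc")
#>       class  n  median    q25    q75
#> 1 increased 12  0.5495  0.130  0.906
#> 2 unchanged 42  0.0176 -0.252  0.235
#> 3 decreased  6 -0.4338 -0.556 -0.223

out$apa$control
#> <apa_result> 32 loops (28 skipped), P2LL = 3.071
```

The recovered accessibility–contact correlation (0.57) tracks the planted
target of 0.6; domains planted with increased accessibility show a
positive median contact change; and APA recovers the planted 3-fold
loop-pixel enrichment. `run_pipeline()` also accepts a directory written
by `write_dataset()` (or by any upstream pipeline producing the same
formats) and, given `outdir=`, writes the per-domain/per-loop/eRNA tables,
the resampling JSON, and a log that accounts for every record entering
each filter. A thin command-line wrapper lives at
`inst/scripts/domainweaver.R` (`simulate` and `run` subcommands).

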