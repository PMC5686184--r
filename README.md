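# ernapipe

Identification and characterization of transcribed enhancer regions
(eRNAs) from histone-mark peaks and poly(A) RNA tag counts.

Active enhancers carry high H3K27ac and H3K4me1 but low H3K4me3, and a
subset of them are themselves transcribed into polyadenylated eRNAs.
`ernapipe` is for computational genomicists who want that discovery chain
as tested, reusable functions rather than a one-off script stack:

- **Candidate discovery** — replicate-consensus peak merging (strict >70%
  support) and a seven-criterion filter cascade (TSS distance ≥ 1 kb, EST
  promoter evidence, H3K4me1/H3K4me3 z-score rules with z > 5 / z < 3,
  H3K4me1 peak within 2 kb, intergenic, rRNA exclusion) with a full
  per-peak verdict trace.
- **Classification** — exact one-dimensional 2-means on log2(n_i + 1) tag
  counts splits candidates into eRNA regions and weakly-transcribed
  enhancers; the detection threshold is the largest count in the weak
  cluster (30 tags at the reference library), scaled to other libraries
  as `30 × N / 245,647,806`; orientation by stranded tag majority.
- **Catalogue characterization** — cross-cell-type master list of
  non-overlapping elements (≤ 5,000 bp), cell specificity, subsampled
  discovery curves, and Weibull saturation fits
  `y = A(1 − exp(−(x/b)^c))` with asymptote uncertainty.
- **Variant structure impact** — base-pair probability matrices from an
  O(n³) partition-function dynamic program (validated against an
  exhaustive enumeration oracle), RNAsnp-style interval-maximized
  Euclidean distances between wild-type and mutant ensembles in ±200-nt
  windows, empirical p-values, and riboSNitch calls at p < 0.2.
- **Enrichment statistics** — binomial/Fisher motif enrichment with
  z-transforms, one-hop LD expansion at r² > 0.8, and permutation tests
  of SNP enrichment in loci against length-matched random relocation.
- **lncRNA filtering** — the post-assembly cascade (exonic length, FPKM,
  monoexonic, coding flags, ORF > 300 nt, class codes) plus FPKM/Spearman
  expression association.
- **Synthetic data** — generators for every input class with planted
  ground truth (mixture medians 123/4 at high fraction 0.353, Weibull
  catalogue truth, decoys violating exactly one filter criterion each,
  hairpins with disruptive vs neutral SNVs, LD blocks with planted
  enrichment), so the full chain is testable without downloads.

## Worked example

The whole chain on a synthetic genome with 100 planted enhancers plus
labelled decoys:

```r
library(ernapipe)
res <- run_pipeline(sim_config(seed = 5), n_perm = 500, n_null = 60,
                    saturation_samples = 20)
print(res$report, row.names = FALSE)
#>                 quantity    value
#>  consensus H3K27ac peaks      114
#>      candidate enhancers      100
#>             eRNA regions       33
#>           weak enhancers       67
#>            eRNA fraction    33.0%
#>            tag threshold       16
#>   saturation asymptote A   503.42
#>      LD-expanded SNP set      708
#>          enrichment fold    7.491
#>             enrichment p 0.001996
#>         riboSNitch calls        7
```

Reading the numbers: 116 entities were planted; the two low-replicate
decoys die at the consensus step (114 peaks) and the remaining 14 decoys
each fail their designated filter criterion, leaving exactly the 100
planted enhancers as candidates. The 2-means split calls 33 of them eRNA
regions (the planted high-component fraction is 0.353) with a detection
threshold of 16 tags on this small sample. The Weibull fit recovers the
planted catalogue asymptote A = 500 within 1%. The SNP panel was planted
at 8-fold locus enrichment: the permutation test estimates fold 7.5 and
at 500 permutations the p-value bottoms out at its add-one floor
(~0.002). Of 20 scored hairpin SNVs, 7 — stem-breakers — are called
riboSNitches.

Individual stages are plain functions (`consensus_peaks()`,
`filter_candidates()`, `kmeans_classify()`, `fit_weibull()`,
`base_pair_probabilities()`, `permutation_enrichment()`, ...); see the
vignette `vignettes/erna-pipeline-methods.Rmd` for the models, parameter
defaults, and design decisions.

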