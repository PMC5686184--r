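---
title: "Methods: identifying and characterizing transcribed enhancer regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and characterizing transcribed enhancer regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ernapipe)
```

## Overview

Enhancers marked by H3K27ac produce, in a subset of cases, polyadenylated
non-coding transcripts (eRNAs). `ernapipe` implements the computational
chain that turns histone-mark peak sets and poly(A) RNA tag positions into
an eRNA catalogue, characterizes catalogues across cell types, and scores
the structural impact of disease variants on RNAs inside those regions.
Every stage is exercised on synthetic data with known ground truth; this
vignette records the models, the tunable parameters, and the design
decisions taken where more than one faithful choice existed.

## Coordinate conventions

All intervals are 0-based half-open (the BED convention); GTF input is
converted on read. The TSS of a minus-strand gene is its rightmost
annotated base. The distance from an interval to a point is zero when the
point is covered and otherwise the gap to the nearest covered base.
Chromosome names pass through verbatim. These conventions are internal
choices — peak callers and annotation sources do not agree on one — and
all readers/writers convert at the boundary.

## Candidate-enhancer discovery

Peaks from replicated ChIP-seq are first reduced to consensus peaks:
overlapping peaks (single-linkage, at least 1 bp) are clustered across
replicates and a cluster is kept only when strictly more than 70% of the
replicates contribute to it, reported as the union span. A cluster seen in
2 of 3 replicates (66.7%) is therefore dropped.

Consensus H3K27ac peaks then pass a seven-criterion cascade: (1) at least
1 kb from every annotated TSS; (2) no spliced EST whose 5' end lies within
2 kb of the peak and which spans a TSS — a promoter-proximity proxy; (3)
not abnormally enriched for *both* H3K4me1 and H3K4me3 (z > 5 for both,
the "five sigma" rule) in a 2-kb window centred on the peak; (4) H3K4me3
z < 3 in the same window; (5) an H3K4me1 consensus peak within 2 kb;
(6) intergenic; (7) not overlapping rRNA genes.

Three details are deliberate choices rather than forced ones. First, the
z-score population is the set of H3K27ac peaks surviving criteria 1–2:
criteria 3–4 compare a peak against its peers, and peaks already known to
be promoter-proximal would distort the reference distribution. Second,
"within 2 kb" is measured edge-to-edge between intervals. Third,
criteria 3–7 are all evaluated for every peak surviving 1–2, so the filter
trace carries a complete verdict vector and `first_fail` is the
lowest-numbered failing criterion; because the criteria are conjunctive,
the survivor set does not depend on evaluation order.

## Classification into eRNA regions and weakly-transcribed enhancers

Poly(A) tags are counted in the half-open ±1 kb window around each
candidate's midpoint, and candidates are clustered on `log2(n + 1)` by
two-means. One-dimensional two-means has a global optimum at a contiguous
split of the sorted values, so `kmeans_classify()` scans all splits
(placed only between distinct values, so tied counts never straddle the
boundary) and minimizes the within-cluster sum of squares exactly — no
Lloyd iteration, no seeding, fully deterministic. The detection threshold
is the maximum raw count in the low cluster; at the reference library it
is 30 tags, and other libraries use the depth-corrected threshold
`30 × N / 245,647,806` with the strict comparison `n > threshold`
(fractional thresholds are allowed). Transcription orientation is the
strand holding strictly more tags in the counting window, with `"."` on
ties, including the 0/0 case.

## Catalogues, specificity and saturation

Catalogues from many cell types merge into a master list of
non-overlapping elements capped at 5,000 bp; merged spans longer than the
cap are split into `ceiling(L / 5000)` equal chunks. Equal chunks are a
deterministic choice — any split that respects the cap yields the same
coverage and count. Cell specificity is the number of cell types whose
regions overlap an element.

The discovery curve (mean element count and coverage over random
x-subsets of cell types, sampled without replacement within a subset) is
fit with the saturating form `y = A(1 − exp(−(x/b)^c))` by
Levenberg–Marquardt. `A` is the asymptote (total discoverable elements),
`b` the scale in cell types, `c` the shape. The standard deviation of `A`
comes from the linearized covariance of the fit by default, with a
residual-bootstrap alternative behind `sd_method = "bootstrap"`. The
synthetic generator plants the truth exactly: each element receives a
per-cell inclusion probability `1 − exp(−λ)` with `λ` equal to `1/b`
(shape 1) or `1/b` times a one-sided stable(c) variate (shape < 1,
Kanter's sampler), which makes the expected curve exactly Weibull-shaped.
Shapes above 1 are not completely monotone and cannot arise from
independent element-to-cell assignment, so the generator rejects them.

Two auxiliary rules used when merging structure-model hits: calls
supported by at least two call sets (set-level, single-linkage overlap)
are retained; hits with the same model label whose ends both shift by at
most 10 bp collapse onto the cluster's first representative. The 10-bp
default quantifies "a few bases"; it is configurable.

## Enrichment statistics

Motif enrichment uses an upper-tail binomial test against the genome
background and a two-sided Fisher exact test against weakly-transcribed
enhancers; p-values map to z-scores through the standard normal quantile,
capped at ±8. The Fisher test is two-sided by choice (one-sided would
presuppose the direction). SNP sets expand through linkage disequilibrium
by a single hop over pairs with r² strictly above 0.8 — no transitive
closure, matching how strong-LD proxies are reported.

Permutation enrichment counts SNPs inside loci and compares against
length-matched random loci relocated uniformly (non-overlapping) within a
domain. The domain is treated as a single concatenated coordinate line,
which preserves the locus length multiset exactly and makes placement
O(m log m) per permutation; passing the eRNA-region set as the domain
keeps the null inside eRNA context, passing whole chromosomes gives
genome-wide relocation. The p-value uses the add-one rule
`(1 + #{null ≥ obs}) / (n_perm + 1)` and is never zero.

## RNA structure and riboSNitch scoring

Base-pair probabilities are computed over the Boltzmann ensemble of
pseudoknot-free structures by an O(n³) inside–outside dynamic program
(Rcpp, long-double accumulators with per-base rescaling; windows of a few
hundred nt fold in well under a second). The energy model is a simple
pair-plus-stacking model over the six canonical pairs (defaults GC −3,
AU −2, GU −1, stack −1 kcal/mol, RT 0.616, minimum loop 3, no
lonely-pair penalty). This is deliberate: riboSNitch scoring compares a
wild-type and a mutant ensemble under the *same* model, so a consistent
ensemble matters and full nearest-neighbour thermodynamics does not; the
model is pluggable through `energy_model()`. An exhaustive enumeration
oracle (`enumerate_structures_oracle()`, guarded at 25 nt) lists every
structure, computes the exact partition function by summation, and is the
independent reference the dynamic program is tested against elementwise
to 1e-9.

An SNV is scored by extracting ±200 nt around it (clipped, not discarded,
at sequence ends), folding wild-type and mutant, and maximizing the
Euclidean distance `d(i,j) = sqrt(Σ_{i≤k<l≤j} (P_wt − P_mt)²)` over all
intervals containing the SNV with span at least `min_interval` (default
50 nt, the published default of the reference tool). Taken literally the
distance is monotone under interval inclusion, so the unnormalized
maximum is attained by the full window; a length-normalized variant
(`normalized = TRUE`) makes the maximizing interval informative. The
empirical p-value compares the observed `d_max` against random SNVs
(uniform position, uniform non-reference base) on the same window — a
same-sequence null rather than precomputed GC/length background tables —
and calls riboSNitches at p < 0.2, strict. Because windowing bounds every
fold at ≤ 401 nt, no separate long-sequence mode is needed; folding of
sequences beyond ~2,000 nt is out of scope.

## lncRNA transcript filtering

Assembled transcript predictions are filtered in a fixed cascade: exonic
length < 200 bp; maximum FPKM = 0; monoexonic; coding potential flagged
by either external predictor; longest ORF > 300 nt; class code outside
{x, i, j, u, o}. The ORF scan covers the three forward frames only
(assembled transcripts are oriented) and counts ATG-to-stop spans
including the stop codon; an ATG without an in-frame stop is not an ORF.
Expressed genes are those exceeding FPKM 1 (strict) in at least one
sample. FPKM is the standard
`count / ((length/1000) · (total/10⁶))`, and eRNA regions use their own
interval length. Region-gene association uses the TSS nearest the region
midpoint with a leftmost tie-break — the minimal faithful rule where
chromatin-interaction data are absent.

## Synthetic data: what it emulates, and what it does not

The generators plant ground truth for every stage. The genome bundle lays
genes, rRNA, true enhancers and decoys into separate 12-kb slots so that
spacing constraints hold by construction, and each decoy class violates
exactly one criterion; the mark-signal magnitudes (Poisson λ 50/30 at
ordinary peaks, 5,000 and 2,750 at the z-score decoys) were chosen by the
population-z arithmetic so the planted violations clear their thresholds
with margin. rRNA genes are kept out of the TSS and gene-body tracks so
the rRNA decoy tests criterion 7 in isolation. Tag counts draw from the
two-component log-normal mixture (medians 123 and 4, high fraction
0.353); the component sigmas (0.85 and 0.95 in natural log) are not
constrained by any reported dispersion and were set so the components
overlap slightly — with them, the exact two-means threshold lands near
~23 tags, within the band expected from the mixture overlap. LD r² values
are drawn from per-block Beta distributions rather than simulated
haplotypes, because the pipeline consumes r² values only.

One structural constraint deserves note: with `n_d` planted outliers among
`N` peaks, the attainable population z-score is about
`sqrt((N − n_d)/n_d)`, so the five-sigma decoy class requires an outlier
fraction below roughly 1/26. The bundle generator predicts the planted
z-scores analytically and refuses configurations whose decoys could not
violate their criterion (in practice, fewer than ~50 true enhancers per
decoy at the default two decoys per class).

Passing tests on these inputs demonstrate the correctness of the
*computational chain* — filters, classifier, fits, statistics — under the
stated statistical structure. They do not demonstrate robustness to
features of real data the generators omit: irregular peak shapes,
copy-number and mappability artefacts, overdispersed tag noise,
haplotype-structured LD, or RNA structures beyond clean stem-loops.

## Problem sizes and numerical choices

The shipped tests run the bundle at 100 true enhancers with 2 decoys per
class, the classifier at the reference 2,373 candidates over 100 seeds,
saturation at A = 500 over 30 cell types with 20-subset Monte-Carlo
averages and 20 seeds, enrichment at 500 disease SNPs with 20,000
permutations, structure checks at 100 random sequences up to 18 nt
against the enumeration oracle, and riboSNitch calibration at 120
p-values with 60 null draws each. Weibull fitting starts from
`A = 1.1·max(y), b = median(x), c = 1` with positive lower bounds;
degenerate (constant) curves either fail with diagnostics or return a
flagged covariance. Two-means refuses all-identical counts; z-scoring
refuses zero-variance populations; the partition function refuses
non-ACGU characters, naming the offending position.

## Known limitations

The energy model is not Turner-accurate and the riboSNitch p-values are
not comparable to the reference tool's table-based values — only the
ranking and calibration properties are claimed. The saturation generator
cannot realize shapes c > 1. Permutation relocation treats the domain as
concatenated, so a relocated locus may correspond to a split region when
mapped back to genomic coordinates; counting happens in concatenated
space, which keeps the null exact for the statistic used. Real-data
catalogue sizes depend on external resources (alignments, covariance
models, GWAS panels) that are outside this package's scope.
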