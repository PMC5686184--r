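Package: ernapipe
Title: Identification and Characterization of Transcribed Enhancer (eRNA) Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for identifying transcribed enhancer regions (eRNAs)
    from histone-mark peak sets and poly(A) RNA tag counts, and for
    characterizing the resulting catalogues. Candidate enhancers are located
    by a replicate-consensus merge of H3K27ac peaks followed by a
    seven-criterion filter cascade (distance to transcription start sites,
    EST evidence, H3K4me1/H3K4me3 enrichment z-scores, intergenic and
    rRNA exclusion). Candidates are split into eRNA regions and
    weakly-transcribed enhancers by exact one-dimensional K-means on
    log2-transformed tag counts, with a sequencing-depth-corrected detection
    threshold. Catalogues across cell types are summarized by a
    non-overlapping master list, cell-specificity counts, and subsampled
    saturation curves extrapolated with a Weibull fit. Downstream modules
    score disease SNP effects on RNA secondary structure (riboSNitch calls
    from partition-function base-pair probabilities), expand SNP sets through
    linkage disequilibrium, test SNP enrichment in genomic loci by
    permutation, filter assembled transcripts to candidate lncRNAs, and
    compute FPKM/Spearman expression associations. A synthetic-data module
    generates inputs with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    data.table,
    jsonlite,
    minpack.lm,
    Rcpp,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
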