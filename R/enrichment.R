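#' Motif-enrichment statistics: binomial, Fisher, z-transform
#'
#' Two complementary tests for a motif observed in `k_erna` of `n_erna`
#' eRNA regions: an upper-tail binomial test against the genome-background
#' rate `p_background`, and a two-sided Fisher exact test against the
#' weakly-transcribed enhancers (`k_weak` of `n_weak`). Both p-values are
#' mapped to z-scores through the standard normal quantile, capped at +/- 8
#' to avoid infinities at p ~ 0 or 1.
#'
#' @param k_erna,n_erna motif hits and total regions in the eRNA set.
#' @param k_weak,n_weak same for the weakly-transcribed set.
#' @param p_background genome background hit probability in (0, 1).
#' @return list: `binomial_p` (P(X >= k_erna)), `fisher_p` (two-sided),
#'   `z_binomial`, `z_fisher`.
#' @export
motif_enrichment_stats <- function(k_erna, n_erna, k_weak, n_weak,
                                   p_background) {
  if (k_erna > n_erna || k_weak > n_weak || k_erna < 0 || k_weak < 0)
    stop("invalid contingency counts: need 0 <= k <= n in both groups")
  if (p_background <= 0 || p_background >= 1)
    stop("p_background must lie strictly inside (0, 1)")
  binom_p <- stats::pbinom(k_erna - 1, n_erna, p_background,
                           lower.tail = FALSE)
  tab <- matrix(c(k_erna, n_erna - k_erna, k_weak, n_weak - k_weak),
                nrow = 2, byrow = TRUE)
  fisher_p <- stats::fisher.test(tab)$p.value
  p_to_z <- function(p) max(-8, min(8, stats::qnorm(1 - p)))
  list(binomial_p = binom_p, fisher_p = fisher_p,
       z_binomial = p_to_z(binom_p), z_fisher = p_to_z(fisher_p))
}

#' One-hop linkage-disequilibrium expansion of a SNP set
#'
#' Adds every SNP linked to a seed SNP by an LD pair with r-squared
#' strictly above the threshold. Expansion is a single hop: SNPs reached
#' only through a chain of pairs are not added (no transitive closure).
#'
#' @param seed_snps character vector of seed SNP ids.
#' @param ld_pairs data.frame with `snp_a`, `snp_b`, `r2` (unordered pairs).
#' @param r2_threshold strong-LD cutoff (default 0.8, strict `>`).
#' @return character vector: seeds plus their strong-LD partners.
#' @export
ld_expand <- function(seed_snps, ld_pairs, r2_threshold = 0.8) {
  if (r2_threshold < 0 || r2_threshold > 1)
    stop("r2_threshold must be in [0, 1]")
  if (is.null(ld_pairs) || nrow(ld_pairs) == 0L) return(unique(seed_snps))
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(ld_pairs)))
  strong <- ld_pairs[ld_pairs$r2 > r2_threshold, , drop = FALSE]
  linked <- c(strong$snp_b[strong$snp_a %in% seed_snps],
              strong$snp_a[strong$snp_b %in% seed_snps])
  unique(c(seed_snps, linked))
}

## internal: map a merged domain to a concatenated coordinate line.
## Returns offsets so that a genomic position maps to
## concat = pos - start_d + offset_d of its containing domain piece.
concat_domain <- function(domain) {
  d <- merge_intervals(domain)
  d <- d[order(d$chrom, d$start), , drop = FALSE]
  len <- d$end - d$start
  d$offset <- cumsum(c(0, len[-length(len)]))
  attr(d, "total_len") <- sum(len)
  d
}

concat_positions <- function(chrom, pos, dom) {
  out <- rep(NA_real_, length(pos))
  for (i in seq_len(nrow(dom))) {
    inside <- chrom == dom$chrom[i] & pos >= dom$start[i] & pos < dom$end[i]
    out[inside] <- pos[inside] - dom$start[i] + dom$offset[i]
  }
  out
}

#' Permutation test of SNP enrichment in genomic loci
#'
#' The observed statistic is the number of SNPs falling inside the loci.
#' Each permutation relocates a length-matched set of non-overlapping random
#' loci uniformly within the domain and recounts. Relocation treats the
#' (merged) domain as one concatenated coordinate line, which preserves the
#' locus length multiset exactly and keeps permuted loci inside the domain;
#' passing the whole genome as `domain` gives genome-wide relocation,
#' passing the eRNA-region set restricts the null to eRNA context.
#'
#' The p-value uses the add-one rule `(1 + #(null >= observed)) /
#' (n_perm + 1)` and is therefore never zero.
#'
#' @param snps data.frame with `chrom`, `pos` (0-based positions).
#' @param loci interval data.frame of the loci of interest; must lie inside
#'   the domain.
#' @param domain interval data.frame of the relocatable space.
#' @param n_perm number of permutations (>= 100).
#' @return object of class `enrichment_result`: `observed`, `null_draws`,
#'   `p_value`, `fold` (observed over mean null).
#' @export
permutation_enrichment <- function(snps, loci, domain, n_perm = 10000) {
  stopifnot(all(c("chrom", "pos") %in% names(snps)))
  validate_gintervals(loci)
  if (n_perm < 100) stop("n_perm must be at least 100")
  dom <- concat_domain(domain)
  L <- attr(dom, "total_len")

  loci_start_c <- concat_positions(loci$chrom, loci$start, dom)
  loci_last_c <- concat_positions(loci$chrom, loci$end - 1L, dom)
  if (anyNA(loci_start_c) || anyNA(loci_last_c))
    stop("all loci must lie inside the domain")
  lens <- loci$end - loci$start
  free <- L - sum(lens)
  if (free < 0)
    stop("domain too small to place ", nrow(loci), " loci of total length ",
         sum(lens))

  snp_c <- sort(concat_positions(snps$chrom, snps$pos, dom))
  snp_c <- snp_c[!is.na(snp_c)]

  count_in <- function(starts, lens) {
    hi <- findInterval(starts + lens - 1e-9, snp_c)
    lo <- findInterval(starts - 1e-9, snp_c)
    sum(hi - lo)
  }
  observed <- count_in(loci_start_c, lens)

  m <- length(lens)
  shift <- cumsum(c(0, lens[-m]))
  null_draws <- vapply(seq_len(n_perm), function(p) {
    starts <- sort(stats::runif(m, 0, free)) + shift
    count_in(starts, lens)
  }, numeric(1))

  p <- (1 + sum(null_draws >= observed)) / (n_perm + 1)
  structure(list(observed = observed, null_draws = null_draws,
                 p_value = p,
                 fold = observed / mean(null_draws)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> observed = %d, mean null = %.2f, fold = %.2f, p = %.3g (%d perms)\n",
              x$observed, mean(x$null_draws), x$fold, x$p_value,
              length(x$null_draws)))
  invisible(x)
}
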