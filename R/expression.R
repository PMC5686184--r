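#' Fragments per kilobase of model per million mapped fragments
#'
#' `fpkm = count / ((length_bp / 1000) * (total_fragments / 1e6))`.
#'
#' @param count fragment count on the feature (>= 0).
#' @param length_bp feature (exon-model) length in bp (> 0).
#' @param total_fragments library size (> 0).
#' @return FPKM value.
#' @export
compute_fpkm <- function(count, length_bp, total_fragments) {
  if (any(length_bp <= 0)) stop("length_bp must be > 0")
  if (any(total_fragments <= 0)) stop("total_fragments must be > 0")
  count / ((length_bp / 1000) * (total_fragments / 1e6))
}

#' Associate a region with its nearest gene by TSS distance
#'
#' The gene whose TSS is closest to the region midpoint wins; equidistant
#' TSSs are broken in favour of the leftmost TSS position.
#'
#' @param region 1-row interval data.frame.
#' @param ann an [annotation()] with a TSS on the region's chromosome.
#' @return the associated `gene_id`.
#' @export
associate_nearest_gene <- function(region, ann) {
  stopifnot(nrow(region) == 1L)
  tss <- ann$tss[ann$tss$chrom == region$chrom, , drop = FALSE]
  if (nrow(tss) == 0L)
    stop("no gene to associate on chromosome ", region$chrom)
  center <- floor((region$start + region$end) / 2)
  d <- abs(tss$pos - center)
  cand <- which(d == min(d))
  cand <- cand[which.min(tss$pos[cand])]
  tss$gene_id[cand]
}

#' Spearman rank correlation between two expression profiles
#'
#' Rank-based correlation with midranks for ties. A constant input vector
#' has no defined rank correlation and raises an error rather than
#' returning NA silently.
#'
#' @param x,y numeric vectors of equal length (>= 3), e.g. FPKM values of
#'   an eRNA region and its associated gene across cell types.
#' @return rho in `[-1, 1]`.
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

#' eRNA-gene expression correlation table
#'
#' For each region: nearest-gene association, its own FPKM profile and the
#' gene's FPKM profile across cell types, and their Spearman correlation.
#'
#' @param regions interval data.frame of eRNA regions (rows named or with a
#'   `region_id` column).
#' @param region_fpkm,gene_fpkm numeric matrices (features x cell types);
#'   `gene_fpkm` rows must be named by `gene_id`.
#' @param ann an [annotation()].
#' @return data.frame with `region_id`, `gene_id`, `rho`.
#' @export
correlate_erna_genes <- function(regions, region_fpkm, gene_fpkm, ann) {
  validate_gintervals(regions)
  stopifnot(nrow(region_fpkm) == nrow(regions))
  ids <- if ("region_id" %in% names(regions)) regions$region_id
         else seq_len(nrow(regions))
  out <- lapply(seq_len(nrow(regions)), function(i) {
    g <- associate_nearest_gene(regions[i, ], ann)
    rho <- if (g %in% rownames(gene_fpkm))
      spearman_correlation(region_fpkm[i, ], gene_fpkm[g, ]) else NA_real_
    data.frame(region_id = ids[i], gene_id = g, rho = rho)
  })
  do.call(rbind, out)
}
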