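#' Format a ratio as a percentage string
#'
#' `100 * numerator / denominator`, rounded half-away-from-zero to one
#' decimal place and suffixed with `%` — the convention used throughout the
#' pipeline's report lines (e.g. 837 of 2,373 prints as "35.3%").
#'
#' @param numerator,denominator the ratio; `denominator` must be > 0.
#' @return string like `"35.3%"`.
#' @export
format_percentage <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be > 0")
  x <- 100 * numerator / denominator
  r <- sign(x) * floor(abs(x) * 10 + 0.5) / 10
  sprintf("%.1f%%", r)
}

#' Run the full pipeline on a synthetic bundle
#'
#' End-to-end orchestration on generated data: replicate-consensus peaks,
#' the seven-criterion filter cascade, tag counting and exact two-means
#' classification with orientation, catalogue series with saturation fit,
#' SNP panel with permutation enrichment, and riboSNitch scoring of hairpin
#' cases. Stage sizes are controlled by `cfg`; the permutation and
#' structure stages accept their own size arguments so quick runs stay
#' quick.
#'
#' @param cfg a [sim_config()].
#' @param n_perm permutations for the enrichment stage.
#' @param n_null null draws per SNV for riboSNitch p-values.
#' @param saturation_samples random subsets per x for the saturation curve.
#' @param outdir optional directory for TSV/BED/JSON outputs.
#' @return list of stage results plus a `report` data.frame of headline
#'   numbers.
#' @export
run_pipeline <- function(cfg = sim_config(), n_perm = 2000, n_null = 60,
                         saturation_samples = 50, outdir = NULL) {
  bundle <- generate_genome_bundle(cfg)

  k27 <- consensus_peaks(bundle$peaks$h3k27ac, min_fraction = 0.7)
  k4 <- consensus_peaks(bundle$peaks$h3k4me1, min_fraction = 0.7)
  filt <- filter_candidates(k27, k4, bundle$signal$h3k4me1,
                            bundle$signal$h3k4me3, bundle$annotation)

  tagsim <- generate_tag_counts(filt$candidates, cfg)
  cls <- classify_enhancers(filt$candidates, tagsim$tags)
  n_cand <- nrow(filt$candidates)
  n_erna <- sum(cls$table$label == "eRNA")

  catalogs <- generate_catalog_series(cfg)
  curve <- saturation_curve(catalogs, n_samples = saturation_samples)
  wfit <- fit_weibull(curve$x, curve$mean_count)

  erna_loci <- filt$candidates[cls$table$label == "eRNA", , drop = FALSE]
  set.seed(cfg$seed)
  domain <- gintervals(chrom = names(bundle$annotation$chrom_lens),
                       start = 0, end = bundle$annotation$chrom_lens)
  panel <- generate_snp_panel(cfg, erna_loci, domain)
  seeds <- panel$disease$id
  expanded <- ld_expand(seeds, panel$ld_pairs, 0.8)
  snp_tab <- rbind(panel$disease[, c("id", "chrom", "pos")],
                   panel$background[, c("id", "chrom", "pos")])
  enr <- permutation_enrichment(
    snp_tab[snp_tab$id %in% panel$disease$id, c("chrom", "pos")],
    erna_loci, domain, n_perm = n_perm)

  struct <- generate_structure_cases(cfg)
  n_struct <- min(10L, cfg$structure$n_cases)
  sub_snvs <- struct$snvs[struct$snvs$seq_id %in%
                            names(struct$seqs)[seq_len(n_struct)], ]
  set.seed(cfg$seed + 6L)
  snitch <- score_snvs(struct$seqs, sub_snvs, n_null = n_null,
                       min_interval = 20)

  report <- data.frame(
    quantity = c("consensus H3K27ac peaks", "candidate enhancers",
                 "eRNA regions", "weak enhancers", "eRNA fraction",
                 "tag threshold", "saturation asymptote A",
                 "LD-expanded SNP set", "enrichment fold",
                 "enrichment p", "riboSNitch calls"),
    value = c(nrow(k27), n_cand, n_erna, n_cand - n_erna,
              format_percentage(n_erna, n_cand),
              cls$model$threshold_tags, signif(wfit$A, 5),
              length(expanded), signif(enr$fold, 4),
              signif(enr$p_value, 4), sum(snitch$is_ribosnitch)),
    stringsAsFactors = FALSE)

  out <- list(bundle = bundle, consensus = list(h3k27ac = k27, h3k4me1 = k4),
              filter = filt, classification = cls, saturation = wfit,
              curve = curve, panel = panel, enrichment = enr,
              ribosnitch = snitch, report = report)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_bed(k27, file.path(outdir, "consensus_h3k27ac.bed"))
    write_tsv_file(filt$trace, file.path(outdir, "filter_trace.tsv"))
    write_tsv_file(cls$table, file.path(outdir, "classification.tsv"))
    write_tsv_file(curve, file.path(outdir, "saturation_curve.tsv"))
    jsonlite::write_json(list(A = wfit$A, b = wfit$b, c = wfit$c,
                              r2 = wfit$r2, A_sd = wfit$A_sd),
                         file.path(outdir, "weibull_fit.json"),
                         auto_unbox = TRUE)
    write_tsv_file(snitch, file.path(outdir, "ribosnitch.tsv"))
    write_tsv_file(report, file.path(outdir, "report.tsv"))
  }
  out
}
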