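#' Replicate-consensus peaks
#'
#' Pools peaks from all replicates, clusters them by single-linkage (>= 1 bp
#' overlap) and keeps clusters supported by strictly more than
#' `min_fraction` of the replicates. The reported span of a kept cluster is
#' the union of its member peaks.
#'
#' @param replicate_sets list of interval data.frames, one per replicate; an
#'   empty data.frame is a valid replicate with zero peaks.
#' @param min_fraction support threshold; a cluster present in exactly this
#'   fraction of replicates (e.g. 0.7) is dropped (strict `>`).
#' @return interval data.frame with a `replicate_support` column.
#' @export
consensus_peaks <- function(replicate_sets, min_fraction = 0.7) {
  stopifnot(length(replicate_sets) >= 1)
  n_rep <- length(replicate_sets)
  nonempty <- which(vapply(replicate_sets, nrow, 1L) > 0L)
  if (length(nonempty) == 0L) {
    out <- gintervals()
    out$replicate_support <- numeric(0)
    return(out)
  }
  pooled <- do.call(rbind, lapply(nonempty, function(i) {
    df <- replicate_sets[[i]][, c("chrom", "start", "end")]
    df$strand <- "."
    df$rep <- i
    df
  }))
  clusters <- merge_intervals(pooled)
  hits <- GenomicRanges::findOverlaps(as_granges0(pooled),
                                      as_granges0(clusters))
  support <- vapply(seq_len(nrow(clusters)), function(ci) {
    members <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == ci]
    length(unique(pooled$rep[members])) / n_rep
  }, numeric(1))
  keep <- support > min_fraction
  out <- clusters[keep, , drop = FALSE]
  out$replicate_support <- support[keep]
  rownames(out) <- NULL
  out
}

#' Standardize raw enrichment values to z-scores
#'
#' Uses the population standard deviation (divisor n, not n - 1), so that
#' the z-scores of the peak population have mean 0 and standard deviation 1
#' exactly.
#'
#' @param values numeric vector of raw window enrichments (>= 2 values).
#' @return data.frame with columns `raw` and `z`, input order preserved.
#' @export
zscore_standardize <- function(values) {
  if (length(values) < 2L)
    stop("z-score standardization needs at least 2 values")
  mu <- mean(values)
  sd_pop <- sqrt(mean((values - mu)^2))
  if (sd_pop == 0)
    stop("degenerate population: all enrichment values identical")
  data.frame(raw = values, z = (values - mu) / sd_pop)
}

## internal: gap in bp between [s1,e1) and [s2,e2); 0 if they share a base
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

#' Seven-criterion candidate-enhancer filter cascade
#'
#' Starting from consensus H3K27ac peaks, a peak is retained as a candidate
#' enhancer only if it passes, in order:
#' \enumerate{
#'   \item at least `tss_distance` bp away from every annotated TSS;
#'   \item no spliced EST with a 5' end within `est_window` bp of the peak
#'     that also spans (strictly contains) an annotated TSS;
#'   \item not abnormally enriched for \emph{both} H3K4me1 and H3K4me3
#'     (z-score > `z_high` for both marks, the "five sigma" rule) in a 2-kb
#'     window centred on the peak;
#'   \item H3K4me3 z-score strictly below `z_max` in the same window;
#'   \item an H3K4me1 consensus peak within `k4me1_window` bp;
#'   \item intergenic (no overlap with any gene body);
#'   \item no overlap with annotated rRNA genes.
#' }
#' Z-scores are computed over the population of H3K27ac peaks surviving
#' criteria 1-2 (population sd). Criteria 3-7 are all evaluated for every
#' such peak so the returned trace carries a full verdict vector;
#' `first_fail` is the lowest-numbered failing criterion.
#'
#' @param h3k27ac consensus H3K27ac peak data.frame (see [consensus_peaks()]).
#' @param h3k4me1_peaks consensus H3K4me1 peak data.frame.
#' @param k4me1_signal,k4me3_signal [tag_set()]s of mark signal (window
#'   enrichment is the tag count in the 2-kb centred window).
#' @param ann an [annotation()].
#' @param tss_distance,est_window,k4me1_window,z_high,z_max,signal_halfwidth
#'   thresholds; defaults are the pipeline's reference values.
#' @return list with `candidates` (surviving peaks, with `candidate_id`) and
#'   `trace` (one row per input peak: verdicts `c1..c7`, z-scores,
#'   `first_fail`, `kept`).
#' @export
filter_candidates <- function(h3k27ac, h3k4me1_peaks,
                              k4me1_signal, k4me3_signal, ann,
                              tss_distance = 1000, est_window = 2000,
                              k4me1_window = 2000, z_high = 5, z_max = 3,
                              signal_halfwidth = 1000) {
  validate_gintervals(h3k27ac)
  n <- nrow(h3k27ac)
  if (n == 0L) stop("no H3K27ac peaks supplied")

  c1 <- c2 <- c3 <- c4 <- c5 <- c6 <- c7 <- rep(NA, n)
  z1 <- z3 <- rep(NA_real_, n)

  ## criterion 1: >= tss_distance from every TSS
  for (i in seq_len(n))
    c1[i] <- distance_to_nearest_tss(h3k27ac[i, ], ann) >= tss_distance

  ## criterion 2: EST 5' end near the peak that spans a TSS
  est <- ann$est_records
  spans_tss <- if (nrow(est) > 0L) vapply(seq_len(nrow(est)), function(e) {
    tss <- ann$tss[ann$tss$chrom == est$chrom[e], , drop = FALSE]
    any(tss$pos > est$start[e] & tss$pos < est$end[e] - 1L)
  }, logical(1)) else logical(0)
  for (i in seq_len(n)) {
    near <- est$chrom == h3k27ac$chrom[i] &
      pmax(0, h3k27ac$start[i] - est$five_prime,
           est$five_prime - (h3k27ac$end[i] - 1L)) <= est_window
    c2[i] <- !any(near & spans_tss)
  }

  ## z-score population: peaks surviving criteria 1-2
  pop <- which(c1 & c2)
  if (length(pop) >= 2L) {
    centers <- floor((h3k27ac$start + h3k27ac$end) / 2)
    raw1 <- raw3 <- rep(NA_real_, n)
    for (i in pop) {
      win_s <- max(0, centers[i] - signal_halfwidth)
      win_e <- centers[i] + signal_halfwidth
      raw1[i] <- count_tags_in(k4me1_signal, h3k27ac$chrom[i], win_s, win_e)
      raw3[i] <- count_tags_in(k4me3_signal, h3k27ac$chrom[i], win_s, win_e)
    }
    z1[pop] <- zscore_standardize(raw1[pop])$z
    z3[pop] <- zscore_standardize(raw3[pop])$z
    c3[pop] <- !(z1[pop] > z_high & z3[pop] > z_high)
    c4[pop] <- z3[pop] < z_max

    k4gr <- if (nrow(h3k4me1_peaks) > 0L) as_granges0(h3k4me1_peaks) else NULL
    for (i in pop) {
      c5[i] <- if (is.null(k4gr)) FALSE else {
        same <- h3k4me1_peaks$chrom == h3k27ac$chrom[i]
        any(same & interval_gap(h3k27ac$start[i], h3k27ac$end[i],
                                h3k4me1_peaks$start,
                                h3k4me1_peaks$end) <= k4me1_window)
      }
      gb <- ann$gene_bodies
      c6[i] <- !(nrow(gb) > 0L &&
                   any(gb$chrom == h3k27ac$chrom[i] &
                         gb$start < h3k27ac$end[i] &
                         gb$end > h3k27ac$start[i]))
      rr <- ann$rrna_genes
      c7[i] <- !(nrow(rr) > 0L &&
                   any(rr$chrom == h3k27ac$chrom[i] &
                         rr$start < h3k27ac$end[i] &
                         rr$end > h3k27ac$start[i]))
    }
  } else if (length(pop) > 0L) {
    stop("cannot evaluate criteria 3-4: fewer than 2 peaks survive ",
         "criteria 1-2, so the z-score population is degenerate")
  }

  verdicts <- cbind(c1, c2, c3, c4, c5, c6, c7)
  first_fail <- apply(verdicts, 1, function(v) {
    f <- which(!v)
    if (length(f)) min(f) else NA_integer_
  })
  kept <- is.na(first_fail) & !is.na(c1)
  trace <- data.frame(peak_id = seq_len(n),
                      chrom = h3k27ac$chrom, start = h3k27ac$start,
                      end = h3k27ac$end,
                      c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5,
                      c6 = c6, c7 = c7,
                      z_k4me1 = z1, z_k4me3 = z3,
                      first_fail = first_fail, kept = kept)
  candidates <- h3k27ac[kept, , drop = FALSE]
  if (nrow(candidates)) candidates$candidate_id <- which(kept)
  rownames(candidates) <- NULL
  list(candidates = candidates, trace = trace)
}
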