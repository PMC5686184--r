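#' Structural disruption score of a single-nucleotide variant
#'
#' RNAsnp-style scoring. A window of `window` nt on each side of the SNV is
#' extracted (clipped, not discarded, at the sequence ends), wild-type and
#' mutant base-pair probability matrices are computed, and the Euclidean
#' distance `d(i,j) = sqrt(sum_(i<=k<l<=j) (P_wt(k,l) - P_mt(k,l))^2)` is
#' maximized over all windows `[i, j]` that contain the SNV and span at
#' least `min_interval` nt. With the plain (unnormalized) distance the
#' terms are non-negative, so `d` is non-decreasing under interval
#' inclusion; `normalized = TRUE` divides by interval length, which makes
#' the maximizing interval informative about where the disruption is local.
#'
#' @param seq RNA sequence string.
#' @param pos 0-based SNV position in `seq`.
#' @param ref,alt reference and alternative base; `ref` must match the
#'   sequence and differ from `alt`.
#' @param window flank size in nt on each side of the SNV.
#' @param min_interval minimum interval span in nt (RNAsnp-like default 50).
#' @param em an [energy_model()].
#' @param normalized divide `d` by interval length.
#' @return list: `d_max`, `interval` (1-based positions in the full
#'   sequence), `window_bounds`, `d2_matrix` window squared-difference
#'   matrix (invisible use by the p-value routine).
#' @export
snv_structural_distance <- function(seq, pos, ref, alt, window = 200,
                                    min_interval = 50, em = energy_model(),
                                    normalized = FALSE) {
  codes_check <- encode_rna(seq)
  n <- length(codes_check)
  if (pos < 0 || pos >= n) stop("SNV position outside the sequence")
  ref <- toupper(chartr("T", "U", ref)); alt <- toupper(chartr("T", "U", alt))
  if (substr(chartr("T", "U", toupper(seq)), pos + 1, pos + 1) != ref)
    stop("ref allele does not match the sequence at position ", pos)
  if (alt == ref) stop("alt allele equals ref")

  ws <- max(0L, pos - window)
  we <- min(n, pos + window + 1L)            # half-open, 0-based
  sub_wt <- substr(chartr("T", "U", toupper(seq)), ws + 1, we)
  p_local <- pos - ws + 1L                   # 1-based within window
  sub_mt <- sub_wt
  substr(sub_mt, p_local, p_local) <- alt

  if (nchar(sub_wt) < min_interval)
    stop("window (", nchar(sub_wt), " nt) shorter than min_interval (",
         min_interval, " nt)")

  P_wt <- base_pair_probabilities(sub_wt, em)$p
  P_mt <- base_pair_probabilities(sub_mt, em)$p
  scan <- scan_max_interval((P_wt - P_mt)^2, p_local, min_interval,
                            normalized)
  list(d_max = scan$d_max,
       interval = scan$interval + ws,        # back to full-sequence coords
       window_bounds = c(ws + 1L, we),
       p_wt = P_wt, p_mt = P_mt)
}

## internal: maximize interval distance over [i,j] containing p_local.
## D2 is the symmetric squared-difference matrix; uses a 2-D prefix sum so
## every interval is O(1). Ties resolve to the smallest i then smallest j.
scan_max_interval <- function(D2, p_local, min_interval, normalized = FALSE) {
  n <- nrow(D2)
  S <- apply(apply(D2, 2, cumsum), 1, cumsum)   # S[j, i] = sum D2[1:i, 1:j]
  S <- t(S)
  rect <- function(i, j) {                      # sum over [i..j] x [i..j]
    S[j, j] - (if (i > 1) S[i - 1, j] + S[j, i - 1] - S[i - 1, i - 1] else 0)
  }
  best <- -Inf; best_ij <- c(NA_integer_, NA_integer_)
  for (i in seq_len(p_local)) {
    j_lo <- max(p_local, i + min_interval - 1L)
    if (j_lo > n) next
    for (j in j_lo:n) {
      d <- sqrt(max(0, rect(i, j) / 2))
      if (normalized) d <- d / (j - i + 1L)
      if (d > best + 1e-15) {
        best <- d
        best_ij <- c(i, j)
      }
    }
  }
  if (!is.finite(best)) stop("no interval satisfies the length constraint")
  list(d_max = best, interval = best_ij)
}

#' Empirical p-value of an SNV's structural distance
#'
#' The null distribution is the `d_max` of `n_null` random SNVs drawn on
#' the same window: position uniform over the window, alternative base
#' uniform over the three non-reference bases. The reported p-value is the
#' add-one tail probability `(1 + #(null >= observed)) / (n_null + 1)`.
#'
#' @inheritParams snv_structural_distance
#' @param n_null number of null draws (>= 50).
#' @return list: `p_value`, `d_max`, `interval`, `null_draws`.
#' @export
empirical_structure_pvalue <- function(seq, pos, ref, alt, n_null = 100,
                                       window = 200, min_interval = 50,
                                       em = energy_model(),
                                       normalized = FALSE) {
  if (n_null < 50) stop("n_null must be at least 50")
  obs <- snv_structural_distance(seq, pos, ref, alt, window, min_interval,
                                 em, normalized)
  ws <- obs$window_bounds[1] - 1L            # 0-based window start
  we <- obs$window_bounds[2]
  sub_wt <- substr(chartr("T", "U", toupper(seq)), ws + 1, we)
  P_wt <- obs$p_wt
  wlen <- nchar(sub_wt)

  null_draws <- vapply(seq_len(n_null), function(k) {
    p_loc <- sample.int(wlen, 1)             # 1-based within window
    base <- substr(sub_wt, p_loc, p_loc)
    alt_k <- sample(setdiff(RNA_BASES, base), 1)
    sub_mt <- sub_wt
    substr(sub_mt, p_loc, p_loc) <- alt_k
    P_mt <- base_pair_probabilities(sub_mt, em)$p
    scan_max_interval((P_wt - P_mt)^2, p_loc, min_interval,
                      normalized)$d_max
  }, numeric(1))

  p <- (1 + sum(null_draws >= obs$d_max)) / (n_null + 1)
  list(p_value = p, d_max = obs$d_max, interval = obs$interval,
       null_draws = null_draws)
}

#' Call riboSNitches from structural-distance results
#'
#' An SNV is called a riboSNitch when its empirical p-value is strictly
#' below `p_threshold` (default 0.2).
#'
#' @param results data.frame with a `p_value` column.
#' @param p_threshold call threshold (strict `<`).
#' @return `results` with an added logical `is_ribosnitch` column.
#' @export
call_ribosnitches <- function(results, p_threshold = 0.2) {
  stopifnot(nrow(results) > 0, "p_value" %in% names(results))
  results$is_ribosnitch <- results$p_value < p_threshold
  results
}

#' Score a table of SNVs against their sequences
#'
#' Convenience driver over [snv_structural_distance()],
#' [empirical_structure_pvalue()] and [call_ribosnitches()].
#'
#' @param seqs named character vector of sequences (e.g. [read_fasta()]).
#' @param snvs data.frame with `seq_id`, `pos` (0-based), `ref`, `alt`.
#' @param n_null,window,min_interval,em,p_threshold passed through.
#' @return data.frame: per SNV `d_max`, `interval_start`, `interval_end`,
#'   `p_value`, `is_ribosnitch`.
#' @export
score_snvs <- function(seqs, snvs, n_null = 100, window = 200,
                       min_interval = 50, em = energy_model(),
                       p_threshold = 0.2) {
  stopifnot(all(c("seq_id", "pos", "ref", "alt") %in% names(snvs)))
  rows <- lapply(seq_len(nrow(snvs)), function(i) {
    s <- snvs[i, ]
    r <- empirical_structure_pvalue(seqs[[s$seq_id]], s$pos, s$ref, s$alt,
                                    n_null, window, min_interval, em)
    data.frame(seq_id = s$seq_id, pos = s$pos, ref = s$ref, alt = s$alt,
               d_max = r$d_max, interval_start = r$interval[1],
               interval_end = r$interval[2], p_value = r$p_value)
  })
  call_ribosnitches(do.call(rbind, rows), p_threshold)
}
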