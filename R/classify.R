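#' Count poly(A) RNA tags centred on a candidate enhancer
#'
#' Counts tag positions (both strands) in the half-open window
#' `[center - flank, center + flank)`, where `center` is the midpoint of the
#' candidate interval (floor of the coordinate mean).
#'
#' @param candidate 1-row interval data.frame.
#' @param tags a [tag_set()].
#' @param flank half-width of the counting window in bp.
#' @return integer tag count.
#' @export
count_center_tags <- function(candidate, tags, flank = 1000) {
  stopifnot(nrow(candidate) == 1L)
  center <- floor((candidate$start + candidate$end) / 2)
  count_tags_in(tags, candidate$chrom, center - flank, center + flank)
}

#' Exact two-cluster K-means classification of tag counts
#'
#' Clusters candidate enhancers into eRNA regions and weakly-transcribed
#' enhancers by two-means on `log2(n + 1)` transformed tag counts. One-
#' dimensional two-means has a global optimum at a contiguous split of the
#' sorted values, so the exact optimum is found by scanning all splits
#' (between distinct values) and minimizing the within-cluster sum of
#' squares; no iterative seeding is involved and the result is
#' deterministic.
#'
#' @param counts integer vector of per-candidate tag counts `n_i` (at least
#'   two distinct values).
#' @return an object of class `erna_classifier`: `labels` ("eRNA"/"weak"),
#'   `transformed_counts`, `threshold_tags` (maximum raw count in the weak
#'   cluster), `cluster_medians` (named: high, low), `within_ss`.
#' @export
kmeans_classify <- function(counts) {
  if (any(counts < 0)) stop("tag counts must be non-negative")
  y <- log2(counts + 1)
  o <- order(y)
  ys <- y[o]
  n <- length(ys)
  if (length(unique(ys)) < 2L)
    stop("degenerate clustering: all tag counts identical")

  ## prefix sums give within-SS of every contiguous split in O(n)
  cs <- cumsum(ys); cs2 <- cumsum(ys^2)
  splits <- which(diff(ys) > 0)          # no split inside a tie run
  ss_low <- cs2[splits] - cs[splits]^2 / splits
  ss_high <- (cs2[n] - cs2[splits]) -
    (cs[n] - cs[splits])^2 / (n - splits)
  best <- which.min(ss_low + ss_high)
  s <- splits[best]

  weak_idx <- o[seq_len(s)]
  labels <- rep("eRNA", n)
  labels[weak_idx] <- "weak"
  structure(list(
    labels = labels,
    transformed_counts = y,
    threshold_tags = max(counts[weak_idx]),
    cluster_medians = c(high = stats::median(counts[labels == "eRNA"]),
                        low = stats::median(counts[weak_idx])),
    within_ss = (ss_low + ss_high)[best]),
    class = "erna_classifier")
}

#' @export
print.erna_classifier <- function(x, ...) {
  cat("<erna_classifier> ", sum(x$labels == "eRNA"), " eRNA / ",
      sum(x$labels == "weak"), " weak; threshold_tags = ",
      x$threshold_tags, "; medians = ", x$cluster_medians[["high"]], "/",
      x$cluster_medians[["low"]], "\n", sep = "")
  invisible(x)
}

#' Sequencing-depth-corrected detection threshold
#'
#' Scales the reference tag threshold (30 tags at the reference library of
#' 245,647,806 total tags) linearly with library size, so catalogues built
#' from libraries of different depth use comparable detection cutoffs. The
#' returned threshold may be fractional; counts are compared as
#' `n_i > threshold`.
#'
#' @param total_tags library size N of the target sample (>= 0).
#' @param reference_threshold,reference_total the calibration constants.
#' @return corrected threshold in tags.
#' @export
depth_corrected_threshold <- function(total_tags,
                                      reference_threshold = 30,
                                      reference_total = 245647806) {
  if (total_tags < 0) stop("total_tags must be non-negative")
  reference_threshold * total_tags / reference_total
}

#' Transcription orientation of a region from stranded tags
#'
#' The strand with strictly more tags in the centred counting window wins;
#' ties (including zero tags) give `"."`.
#'
#' @inheritParams count_center_tags
#' @return one of `"+"`, `"-"`, `"."`.
#' @export
assign_orientation <- function(candidate, tags, flank = 1000) {
  stopifnot(nrow(candidate) == 1L)
  center <- floor((candidate$start + candidate$end) / 2)
  np <- count_tags_in(tags, candidate$chrom, center - flank, center + flank, "+")
  nm <- count_tags_in(tags, candidate$chrom, center - flank, center + flank, "-")
  if (np > nm) "+" else if (nm > np) "-" else "."
}

#' Classify candidate enhancers into eRNA regions and weak enhancers
#'
#' Convenience wrapper: counts centred tags for every candidate, runs the
#' exact two-means classifier, and assigns transcription orientation.
#'
#' @param candidates interval data.frame of candidate enhancers.
#' @param tags a [tag_set()] of poly(A) RNA tag positions.
#' @param flank counting half-width in bp.
#' @return list with `table` (one row per candidate: `n_i`, `log2_n1`,
#'   `label`, `orientation`, `threshold`) and `model` (the
#'   `erna_classifier`).
#' @export
classify_enhancers <- function(candidates, tags, flank = 1000) {
  validate_gintervals(candidates)
  counts <- vapply(seq_len(nrow(candidates)), function(i)
    count_center_tags(candidates[i, ], tags, flank), numeric(1))
  model <- kmeans_classify(counts)
  orient <- vapply(seq_len(nrow(candidates)), function(i)
    assign_orientation(candidates[i, ], tags, flank), character(1))
  tab <- data.frame(
    candidate_id = if ("candidate_id" %in% names(candidates))
      candidates$candidate_id else seq_len(nrow(candidates)),
    chrom = candidates$chrom, start = candidates$start,
    end = candidates$end,
    n_i = counts, log2_n1 = model$transformed_counts,
    label = model$labels, orientation = orient,
    threshold = model$threshold_tags)
  list(table = tab, model = model)
}
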