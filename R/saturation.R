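#' Build the cross-cell-type master list of non-overlapping elements
#'
#' Union-merges the regions of all per-cell-type catalogues; merged spans
#' longer than `max_len` bp are split into `ceiling(L / max_len)` equal-
#' length chunks so every element is at most `max_len` bp. Each element's
#' membership is the set of cell types with at least one overlapping region.
#'
#' @param catalogs named list of interval data.frames, one per cell type.
#' @param max_len maximum element length in bp (default 5,000).
#' @return object of class `master_list`: `elements` (intervals with
#'   `element_id` and `membership`, a semicolon-joined cell-type string),
#'   `cell_types`.
#' @export
build_master_list <- function(catalogs, max_len = 5000) {
  stopifnot(length(catalogs) >= 1)
  if (is.null(names(catalogs)))
    names(catalogs) <- paste0("cell", seq_along(catalogs))
  pooled <- do.call(rbind, lapply(catalogs, function(x)
    x[, c("chrom", "start", "end")]))
  merged <- merge_intervals(cbind(pooled, strand = "."))

  ## equal-chunk split of long spans
  pieces <- lapply(seq_len(nrow(merged)), function(i) {
    L <- merged$end[i] - merged$start[i]
    k <- ceiling(L / max_len)
    bounds <- merged$start[i] + round(L * (0:k) / k)
    data.frame(chrom = merged$chrom[i], start = bounds[-(k + 1)],
               end = bounds[-1], strand = ".",
               stringsAsFactors = FALSE)
  })
  elements <- do.call(rbind, pieces)
  elements$element_id <- seq_len(nrow(elements))

  egr <- as_granges0(elements)
  membership <- rep("", nrow(elements))
  member_mat <- matrix(FALSE, nrow(elements), length(catalogs),
                       dimnames = list(NULL, names(catalogs)))
  for (ct in names(catalogs)) {
    cat_df <- catalogs[[ct]]
    if (nrow(cat_df) == 0L) next
    hits <- GenomicRanges::findOverlaps(egr, as_granges0(
      cbind(cat_df[, c("chrom", "start", "end")], strand = ".")))
    member_mat[unique(S4Vectors::queryHits(hits)), ct] <- TRUE
  }
  elements$membership <- apply(member_mat, 1, function(r)
    paste(names(catalogs)[r], collapse = ";"))
  rownames(elements) <- NULL
  structure(list(elements = elements, cell_types = names(catalogs),
                 member_mat = member_mat),
            class = "master_list")
}

#' @export
print.master_list <- function(x, ...) {
  cat("<master_list> ", nrow(x$elements), " elements across ",
      length(x$cell_types), " cell types\n", sep = "")
  invisible(x)
}

#' Cell-type specificity of master-list elements
#'
#' @param ml a [build_master_list()] result.
#' @return list with `counts` (per-element number of cell types), `mean`,
#'   `median`.
#' @export
cell_specificity <- function(ml) {
  stopifnot(inherits(ml, "master_list"))
  counts <- rowSums(ml$member_mat)
  list(counts = counts, mean = mean(counts), median = stats::median(counts))
}

#' Subsampled saturation curve of element count and coverage
#'
#' For each x in 1..n_cells, draws `n_samples` random x-subsets of cell
#' types (without replacement within a subset) and averages the master-list
#' element count and total bp coverage of each subset. At x = n_cells every
#' subset is the full set, so that point is computed once and equals the
#' full master list exactly.
#'
#' @param catalogs named list of per-cell-type interval data.frames (>= 2).
#' @param n_samples random subsets per x; the study-scale default is 20,000
#'   but smaller values give the same expectation with more Monte-Carlo
#'   noise.
#' @param max_len element length cap passed to [build_master_list()].
#' @return data.frame with `x`, `mean_count`, `mean_coverage`.
#' @export
saturation_curve <- function(catalogs, n_samples = 20000, max_len = 5000) {
  stopifnot(length(catalogs) >= 2)
  if (n_samples <= 0) stop("n_samples must be positive")
  n_cells <- length(catalogs)
  ## element count = number of <= max_len chunks of the merged union, and
  ## coverage = union bp; both are independent of membership bookkeeping,
  ## so the full build_master_list() machinery is skipped here
  one <- function(sub) {
    pooled <- data.table::rbindlist(lapply(catalogs[sub], function(x)
      x[, c("chrom", "start", "end")]))
    cnt <- cov <- 0
    for (p in split(pooled, pooled$chrom)) {
      ir <- IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end))
      L <- IRanges::width(ir)
      cnt <- cnt + sum(ceiling(L / max_len))
      cov <- cov + sum(L)
    }
    c(cnt, cov)
  }
  res <- lapply(seq_len(n_cells), function(x) {
    if (x == n_cells) return(one(seq_len(n_cells)))
    draws <- vapply(seq_len(n_samples), function(s)
      one(sample.int(n_cells, x)), numeric(2))
    rowMeans(draws)
  })
  res <- do.call(rbind, res)
  data.frame(x = seq_len(n_cells), mean_count = res[, 1],
             mean_coverage = res[, 2])
}

#' Weibull saturation fit
#'
#' Least-squares fit of the saturating form `y = A * (1 - exp(-(x/b)^c))`
#' to a discovery curve, via Levenberg-Marquardt. The asymptote A estimates
#' the total number (or bp) of discoverable elements; its standard
#' deviation is taken from the linearized parameter covariance of the fit
#' (or by resampling residuals when `sd_method = "bootstrap"`).
#'
#' @param x,y curve points (>= 4; y non-decreasing in expectation).
#' @param sd_method "covariance" (default) or "bootstrap".
#' @param n_boot bootstrap replicates when `sd_method = "bootstrap"`.
#' @return object of class `weibull_fit`: `A`, `b`, `c`, `r2`, `A_sd`,
#'   `fitted`, `residuals`.
#' @export
fit_weibull <- function(x, y, sd_method = c("covariance", "bootstrap"),
                        n_boot = 200) {
  sd_method <- match.arg(sd_method)
  stopifnot(length(x) == length(y), length(x) >= 4)
  df <- data.frame(x = x, y = y)
  start <- list(A = max(y) * 1.1 + 1e-9, b = stats::median(x), c = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - exp(-(x / b)^c)), data = df,
                      start = start, lower = c(1e-12, 1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("weibull fit failed: ", conditionMessage(e),
           " (y range ", paste(signif(range(y), 4), collapse = " .. "), ")"))
  co <- stats::coef(fit)
  res <- stats::resid(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  A_sd <- if (sd_method == "covariance") {
    v <- tryCatch(stats::vcov(fit), error = function(e) NULL)
    if (is.null(v) || !is.finite(v[1, 1])) NA_real_ else sqrt(v[1, 1])
  } else {
    fitted_y <- stats::fitted(fit)
    As <- vapply(seq_len(n_boot), function(b) {
      yb <- fitted_y + sample(res, replace = TRUE)
      fb <- tryCatch(minpack.lm::nlsLM(
        yb ~ A * (1 - exp(-(x / b)^c)), data = data.frame(x = x, yb = yb),
        start = as.list(co), lower = c(1e-12, 1e-12, 1e-12)),
        error = function(e) NULL)
      if (is.null(fb)) NA_real_ else stats::coef(fb)[["A"]]
    }, numeric(1))
    stats::sd(As, na.rm = TRUE)
  }
  structure(list(A = co[["A"]], b = co[["b"]], c = co[["c"]],
                 r2 = r2, A_sd = A_sd,
                 fitted = stats::fitted(fit), residuals = res),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("<weibull_fit> A = %.4g (sd %.3g), b = %.4g, c = %.4g, r2 = %.6f\n",
              x$A, x$A_sd, x$b, x$c, x$r2))
  invisible(x)
}

#' Regions supported by at least two call sets
#'
#' Clusters pooled calls by single-linkage (>= 1 bp overlap) and keeps
#' cluster spans supported by at least `min_sets` distinct input sets.
#'
#' @param call_sets list of >= 2 interval data.frames.
#' @param min_sets support threshold (sets, not individual calls).
#' @return interval data.frame with an `n_sets` column.
#' @export
consensus_calls <- function(call_sets, min_sets = 2) {
  stopifnot(length(call_sets) >= 2)
  cp <- consensus_peaks(call_sets, min_fraction = 0)
  cp$n_sets <- round(cp$replicate_support * length(call_sets))
  cp <- cp[cp$n_sets >= min_sets, , drop = FALSE]
  cp$replicate_support <- NULL
  rownames(cp) <- NULL
  cp
}

#' De-duplicate model hits that differ only by a small coordinate shift
#'
#' Hits carrying the same model label whose start and end coordinates both
#' differ by at most `shift_tol` bp from a cluster's first (representative)
#' hit are collapsed onto that representative.
#'
#' @param hits interval data.frame with a `model` column.
#' @param shift_tol maximum per-end shift in bp counted as "the same hit".
#' @return data.frame of unique representative hits with `n_hits` support.
#' @export
dedup_hits <- function(hits, shift_tol = 10) {
  stopifnot("model" %in% names(hits))
  validate_gintervals(hits)
  out <- list()
  for (m in unique(hits$model)) {
    h <- hits[hits$model == m, , drop = FALSE]
    h <- h[order(h$chrom, h$start, h$end), , drop = FALSE]
    reps <- integer(0)
    count <- integer(0)
    for (i in seq_len(nrow(h))) {
      assigned <- FALSE
      for (r in seq_along(reps)) {
        j <- reps[r]
        if (h$chrom[j] == h$chrom[i] &&
            abs(h$start[j] - h$start[i]) <= shift_tol &&
            abs(h$end[j] - h$end[i]) <= shift_tol) {
          count[r] <- count[r] + 1L
          assigned <- TRUE
          break
        }
      }
      if (!assigned) {
        reps <- c(reps, i)
        count <- c(count, 1L)
      }
    }
    u <- h[reps, , drop = FALSE]
    u$n_hits <- count
    out[[m]] <- u
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
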