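# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation paths they check.

# per-base membership union: total covered bases of a set of intervals
brute_union_bases <- function(df) {
  covered <- unique(unlist(lapply(seq_len(nrow(df)), function(i)
    paste0(df$chrom[i], ":", seq(df$start[i], df$end[i] - 1L)))))
  length(covered)
}

# exhaustive 2-partition K-means oracle in log2(n+1) space
brute_two_means <- function(counts) {
  y <- log2(counts + 1)
  n <- length(y)
  best_ss <- Inf
  best_assign <- NULL
  for (mask in 1:(2^n - 2)) {
    a <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    ss <- sum((y[a] - mean(y[a]))^2) + sum((y[!a] - mean(y[!a]))^2)
    if (ss < best_ss - 1e-12) {
      best_ss <- ss
      best_assign <- a
    }
  }
  high <- if (mean(y[best_assign]) > mean(y[!best_assign])) best_assign else !best_assign
  list(erna = sort(counts[high]), threshold = max(counts[!high]),
       within_ss = best_ss)
}

# exhaustive interval scan for the riboSNitch distance
brute_interval_scan <- function(D2, p_local, min_interval) {
  n <- nrow(D2)
  best <- -Inf
  best_ij <- c(NA, NA)
  for (i in seq_len(p_local)) for (j in p_local:n) {
    if (j - i + 1 < min_interval) next
    d2 <- 0
    for (k in i:(j - 1)) for (l in (k + 1):j) d2 <- d2 + D2[k, l]
    d <- sqrt(d2)
    if (d > best + 1e-15) {
      best <- d
      best_ij <- c(i, j)
    }
  }
  list(d_max = best, interval = best_ij)
}

# rank-statistic AUC (Mann-Whitney)
rank_auc <- function(score, positive) {
  r <- rank(score)
  np <- sum(positive)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * sum(!positive))
}

# tiny annotation used by several unit tests
toy_annotation <- function(tss_pos = c(1000, 5000), chrom = "c1") {
  annotation(tss = data.frame(gene_id = paste0("g", seq_along(tss_pos)),
                              chrom = chrom, pos = tss_pos,
                              strand = "+"))
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")
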