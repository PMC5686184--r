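#' Simple nearest-pair energy model for RNA secondary structure
#'
#' A pair-plus-stacking energy model over the six canonical pairs (Watson-
#' Crick and GU wobble). The model is deliberately coarse: riboSNitch
#' scoring needs a consistent thermodynamic ensemble for comparing wild-type
#' and mutant sequences, not absolute free-energy accuracy, and the model is
#' pluggable (all energies are arguments).
#'
#' @param pair_energies named numeric vector of pair energies in kcal/mol;
#'   names must be exactly the six allowed pairs.
#' @param stack_bonus additional energy for each pair immediately stacked on
#'   an enclosing pair (both `(k,l)` and `(k+1,l-1)` present).
#' @param temperature_RT the Boltzmann factor denominator RT, in kcal/mol
#'   (0.616 corresponds to 37 C).
#' @param min_loop minimum hairpin loop length in nt (>= 3).
#' @return an object of class `energy_model`.
#' @export
energy_model <- function(pair_energies = c(GC = -3, CG = -3, AU = -2,
                                           UA = -2, GU = -1, UG = -1),
                         stack_bonus = -1, temperature_RT = 0.616,
                         min_loop = 3L) {
  allowed <- c("GC", "CG", "AU", "UA", "GU", "UG")
  if (!setequal(names(pair_energies), allowed))
    stop("pair_energies must be named by exactly the six canonical pairs")
  if (min_loop < 3) stop("min_loop must be >= 3")
  if (temperature_RT <= 0) stop("temperature_RT must be > 0")
  structure(list(pair_energies = pair_energies[allowed],
                 stack_bonus = stack_bonus,
                 temperature_RT = temperature_RT,
                 min_loop = as.integer(min_loop)),
            class = "energy_model")
}

RNA_BASES <- c("A", "C", "G", "U")

## internal: sequence string -> 0-based integer codes (A=0 C=1 G=2 U=3)
encode_rna <- function(seq) {
  chars <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  codes <- match(chars, RNA_BASES) - 1L
  if (anyNA(codes))
    stop("invalid RNA character '", chars[which(is.na(codes))[1]],
         "' at position ", which(is.na(codes))[1])
  codes
}

## internal: 4x4 Boltzmann pair-weight matrix (0 where pairing disallowed)
pair_weight_matrix <- function(em) {
  W <- matrix(0, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  for (p in names(em$pair_energies)) {
    a <- substr(p, 1, 1); b <- substr(p, 2, 2)
    W[a, b] <- exp(-em$pair_energies[[p]] / em$temperature_RT)
  }
  W
}

#' Base-pair probability matrix by the partition-function algorithm
#'
#' Computes, for every pair of positions `(k, l)`, the equilibrium
#' probability that bases `k` and `l` pair, summed over the Boltzmann
#' ensemble of all pseudoknot-free secondary structures under the given
#' energy model. Implemented as an O(n^3) inside-outside dynamic program.
#'
#' @param seq RNA sequence (string over ACGU; T accepted and read as U).
#' @param em an [energy_model()].
#' @return an object of class `bpp_matrix`: a list with `n` (sequence
#'   length), `p` (symmetric n x n probability matrix) and `seq`.
#' @examples
#' bp <- base_pair_probabilities("GGGAAAACCC", energy_model())
#' which(bp$p == max(bp$p), arr.ind = TRUE)
#' @export
base_pair_probabilities <- function(seq, em = energy_model()) {
  codes <- encode_rna(seq)
  P <- bpp_partition_cpp(codes, pair_weight_matrix(em),
                         exp(-em$stack_bonus / em$temperature_RT),
                         em$min_loop)
  structure(list(n = length(codes), p = P, seq = seq), class = "bpp_matrix")
}

#' @export
print.bpp_matrix <- function(x, ...) {
  cat("<bpp_matrix> n =", x$n, "; max P =", signif(max(x$p), 4), "\n")
  invisible(x)
}

#' Write a base-pair probability matrix as TSV triplets (k, l, P)
#'
#' Only the upper triangle (k < l) with nonzero probability is written;
#' positions are 1-based.
#' @param bp a `bpp_matrix`.
#' @param path output path.
#' @export
write_bpp_tsv <- function(bp, path) {
  idx <- which(upper.tri(bp$p) & bp$p > 0, arr.ind = TRUE)
  df <- data.frame(k = idx[, 1], l = idx[, 2], p = bp$p[idx])
  df <- df[order(df$k, df$l), ]
  write_tsv_file(df, path)
}

#' Exhaustive enumeration oracle for small sequences
#'
#' Enumerates every pseudoknot-free structure satisfying the minimum-loop
#' constraint, computes each structure's energy (pair energies plus stacking
#' bonuses), and derives the exact partition function and base-pair
#' probability matrix by direct summation. Intended as an independent check
#' of [base_pair_probabilities()]; refuses sequences longer than
#' `max_len` to bound the combinatorial blow-up.
#'
#' @inheritParams base_pair_probabilities
#' @param max_len refusal guard on sequence length.
#' @return list with `structures` (each a 2-column matrix of 1-based paired
#'   positions), `energies`, `Z` and `p` (exact probability matrix).
#' @export
enumerate_structures_oracle <- function(seq, em = energy_model(),
                                        max_len = 25L) {
  codes <- encode_rna(seq)
  n <- length(codes)
  if (n > max_len)
    stop("enumeration oracle refuses sequences longer than ", max_len, " nt")
  W <- pair_weight_matrix(em)
  can_pair <- function(i, j) W[codes[i] + 1L, codes[j] + 1L] > 0

  memo <- new.env(parent = emptyenv())
  enum <- function(i, j) {
    if (j - i < em$min_loop + 1L) return(list(matrix(0L, 0, 2)))
    key <- paste0(i, ",", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- enum(i + 1L, j)                      # i unpaired
    for (k in seq(i + em$min_loop + 1L, j)) {   # i paired with k
      if (!can_pair(i, k)) next
      left <- enum(i + 1L, k - 1L)
      right <- if (k + 1L <= j) enum(k + 1L, j) else list(matrix(0L, 0, 2))
      for (ls in left) for (rs in right)
        out <- c(out, list(rbind(matrix(c(i, k), 1, 2), ls, rs)))
    }
    memo[[key]] <- out
    out
  }
  structures <- enum(1L, n)

  energy_of <- function(pairs) {
    if (nrow(pairs) == 0L) return(0)
    e <- sum(log(W[cbind(codes[pairs[, 1]] + 1L, codes[pairs[, 2]] + 1L)])) *
      (-em$temperature_RT)
    key <- paste(pairs[, 1], pairs[, 2])
    stacked <- sum(paste(pairs[, 1] + 1L, pairs[, 2] - 1L) %in% key)
    e + em$stack_bonus * stacked
  }
  energies <- vapply(structures, energy_of, numeric(1))
  wts <- exp(-energies / em$temperature_RT)
  Z <- sum(wts)
  P <- matrix(0, n, n)
  for (s in seq_along(structures)) {
    pairs <- structures[[s]]
    if (nrow(pairs) == 0L) next
    P[pairs] <- P[pairs] + wts[s]
  }
  P <- P / Z
  P <- P + t(P)
  list(structures = structures, energies = energies, Z = Z, p = P)
}
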