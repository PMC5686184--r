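#' Construct a validated table of genomic intervals
#'
#' The package represents all genomic regions (peaks, enhancers, loci) as a
#' plain `data.frame` with columns `chrom`, `start`, `end` and `strand`,
#' using 0-based half-open coordinates throughout (the BED convention):
#' an interval `[start, end)` covers bases `start .. end - 1`.
#'
#' @param chrom character vector of chromosome names (passed through
#'   verbatim, no "chr" normalization).
#' @param start,end integer-like vectors; `0 <= start < end` is enforced.
#' @param strand one of `"+"`, `"-"`, `"."` (recycled).
#' @param ... further columns (e.g. `name`, `score`) carried along.
#' @return a `data.frame` with at least the four coordinate columns.
#' @export
gintervals <- function(chrom = character(), start = integer(),
                       end = integer(), strand = ".", ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   ...,
                   stringsAsFactors = FALSE)
  validate_gintervals(df)
  df
}

#' @rdname gintervals
#' @param x a data.frame to validate in place.
#' @export
validate_gintervals <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$chrom) | !nzchar(x$chrom)))
    stop("interval chromosome names must be non-empty")
  if (any(x$start < 0))
    stop("interval starts must be >= 0")
  if (any(x$end <= x$start))
    stop("intervals must have end > start (0-based half-open)")
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(x)
}

## internal: 0-based half-open data.frame <-> GRanges (1-based closed)
as_granges0 <- function(x) {
  validate_gintervals(x)
  strand <- if ("strand" %in% names(x)) sub("^\\.$", "*", x$strand) else "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand)
}

from_granges0 <- function(gr) {
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             strand = strand,
             stringsAsFactors = FALSE)
}

#' Merge overlapping intervals into a disjoint sorted set
#'
#' Strand-blind union merge (book-ended intervals sharing only a boundary
#' base are not merged, since `[a,b)` and `[b,c)` are disjoint).
#'
#' @param intervals interval data.frame (see [gintervals()]).
#' @return sorted, pairwise-disjoint interval data.frame covering the same
#'   set of bases; empty input yields an empty frame.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L)
    return(gintervals())
  gr <- as_granges0(intervals)
  BiocGenerics::strand(gr) <- "*"
  merged <- GenomicRanges::reduce(BiocGenerics::sort(gr), min.gapwidth = 0L)
  from_granges0(merged)
}

#' Distance from an interval to the nearest annotated TSS
#'
#' Distance is 0 when a TSS falls inside the interval, otherwise the gap in
#' bp to the nearest covered base.
#'
#' @param iv a single-row interval data.frame.
#' @param ann an [annotation()] object with a non-empty `tss` table.
#' @return non-negative distance in bp.
#' @export
distance_to_nearest_tss <- function(iv, ann) {
  stopifnot(nrow(iv) == 1L)
  validate_gintervals(iv)
  tss <- ann$tss[ann$tss$chrom == iv$chrom, , drop = FALSE]
  if (nrow(tss) == 0L)
    stop("no reference TSS on chromosome ", iv$chrom)
  point_interval_distance(tss$pos, iv$start, iv$end)
}

## distance from point(s) to interval [start,end): 0 if inside
point_interval_distance <- function(pos, start, end) {
  d <- pmax(0, start - pos, pos - (end - 1L))
  min(d)
}

#' Clip a fixed-width window around a position to chromosome bounds
#'
#' @param center 0-based position, must lie on the chromosome.
#' @param half_width window half-width in bp (> 0).
#' @param chrom_len chromosome length in bp.
#' @return a 1-row interval data.frame `[max(0, center - half_width),
#'   min(chrom_len, center + half_width))`.
#' @export
window_around <- function(center, half_width, chrom_len, chrom = "chr") {
  if (half_width <= 0) stop("half_width must be > 0")
  if (center < 0 || center >= chrom_len)
    stop("window center ", center, " outside chromosome [0, ", chrom_len, ")")
  gintervals(chrom = chrom,
             start = max(0, center - half_width),
             end = min(chrom_len, center + half_width))
}

#' Gene/TSS/rRNA/EST annotation bundle
#'
#' @param tss data.frame with `gene_id`, `chrom`, `pos`, `strand`; `pos` is
#'   the transcription start site (for a minus-strand gene this is its
#'   rightmost base).
#' @param gene_bodies interval data.frame with a `gene_id` column.
#' @param rrna_genes interval data.frame of rRNA genes.
#' @param est_records interval data.frame of spliced ESTs with a
#'   `five_prime` column giving the 5'-end position of each EST.
#' @param chrom_lens named numeric vector of chromosome lengths (optional).
#' @return an object of class `erna_annotation`.
#' @export
annotation <- function(tss,
                       gene_bodies = gintervals(),
                       rrna_genes = gintervals(),
                       est_records = NULL,
                       chrom_lens = NULL) {
  stopifnot(is.data.frame(tss),
            all(c("chrom", "pos") %in% names(tss)))
  if (!"gene_id" %in% names(tss))
    tss$gene_id <- paste0("gene", seq_len(nrow(tss)))
  validate_gintervals(gene_bodies)
  validate_gintervals(rrna_genes)
  if (is.null(est_records)) {
    est_records <- gintervals()
    est_records$five_prime <- numeric(0)
  } else {
    validate_gintervals(est_records)
    stopifnot("five_prime" %in% names(est_records))
  }
  if (!is.null(chrom_lens)) {
    bad <- tss$pos < 0 | tss$pos >= chrom_lens[tss$chrom]
    if (any(bad)) stop("TSS outside chromosome bounds: ",
                       paste(tss$gene_id[bad], collapse = ", "))
  }
  structure(list(tss = tss, gene_bodies = gene_bodies,
                 rrna_genes = rrna_genes, est_records = est_records,
                 chrom_lens = chrom_lens),
            class = "erna_annotation")
}

#' @export
print.erna_annotation <- function(x, ...) {
  cat("<erna_annotation> ", nrow(x$tss), " TSSs, ",
      nrow(x$gene_bodies), " gene bodies, ",
      nrow(x$rrna_genes), " rRNA genes, ",
      nrow(x$est_records), " ESTs\n", sep = "")
  invisible(x)
}

#' Stranded tag positions with a library total
#'
#' Holds mapped poly(A) RNA tag 5' positions (or any point signal such as
#' ChIP fragment midpoints). `total_tags` is the library size N, which may
#' exceed the number of stored positions when tags fall outside the stored
#' region of interest.
#'
#' @param positions data.frame with `chrom`, `pos`, `strand`.
#' @param total_tags library size; defaults to `nrow(positions)`.
#' @return an object of class `tag_set`; positions are stored sorted by
#'   chromosome then position.
#' @export
tag_set <- function(positions, total_tags = nrow(positions)) {
  stopifnot(is.data.frame(positions),
            all(c("chrom", "pos") %in% names(positions)))
  if (!"strand" %in% names(positions)) positions$strand <- "."
  if (total_tags < nrow(positions))
    stop("total_tags must be >= number of stored positions")
  positions <- positions[order(positions$chrom, positions$pos), , drop = FALSE]
  rownames(positions) <- NULL
  structure(list(positions = positions, total_tags = total_tags),
            class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat("<tag_set> ", nrow(x$positions), " stored positions, total_tags = ",
      x$total_tags, "\n", sep = "")
  invisible(x)
}

## internal: count tag positions (optionally one strand) inside [start,end)
count_tags_in <- function(tags, chrom, start, end, strand = NULL) {
  p <- tags$positions
  keep <- p$chrom == chrom & p$pos >= start & p$pos < end
  if (!is.null(strand)) keep <- keep & p$strand == strand
  sum(keep)
}
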