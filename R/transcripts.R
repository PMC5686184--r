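#' Longest open reading frame in the sense strand
#'
#' Scans the three forward frames for ATG-to-stop spans and returns the
#' longest, in nucleotides including the stop codon. Assembled transcripts
#' are already oriented, so the reverse strand is not scanned; an ATG with
#' no downstream in-frame stop does not count as an ORF.
#'
#' @param seq DNA or RNA sequence string.
#' @return length in nt of the longest ORF (0 if none).
#' @export
longest_orf_length <- function(seq) {
  s <- chartr("U", "T", toupper(seq))
  n <- nchar(s)
  best <- 0L
  for (frame in 0:2) {
    m <- (n - frame) %/% 3
    if (m < 2) next
    codons <- substring(s, frame + 1 + 3 * (0:(m - 1)),
                        frame + 3 * (1:m))
    starts <- which(codons == "ATG")
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (!length(starts) || !length(stops)) next
    for (st in starts) {
      after <- stops[stops >= st]
      if (length(after)) {
        len <- (after[1] - st + 1L) * 3L
        if (len > best) best <- len
        ## later starts inside this ORF are shorter; keep scanning anyway
      }
    }
  }
  best
}

#' Build transcript records from components
#'
#' @param id,gene_id identifiers.
#' @param exons interval data.frame of the transcript's exons
#'   (non-overlapping; sorted on construction).
#' @param fpkm numeric vector of per-sample FPKM values.
#' @param class_code single cuffcompare-style class code character.
#' @param coding_flag_a,coding_flag_b external coding-potential verdicts
#'   (`TRUE` = predicted coding).
#' @param sequence optional transcript sequence for the ORF rule.
#' @return a one-row data.frame understood by
#'   [filter_lncrna_transcripts()].
#' @export
transcript_record <- function(id, gene_id, exons, fpkm, class_code,
                              coding_flag_a = FALSE, coding_flag_b = FALSE,
                              sequence = NA_character_) {
  validate_gintervals(exons)
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("exons of transcript ", id, " overlap")
  data.frame(id = id, gene_id = gene_id,
             exonic_length = sum(exons$end - exons$start),
             n_exons = nrow(exons),
             max_fpkm = max(fpkm),
             class_code = class_code,
             coding_flag_a = coding_flag_a,
             coding_flag_b = coding_flag_b,
             sequence = sequence,
             stringsAsFactors = FALSE)
}

#' Post-assembly lncRNA filter cascade
#'
#' Drops transcript predictions, in order, when they have: total exonic
#' length < `min_exonic` bp ("short_exonic"); maximum FPKM of exactly 0
#' ("zero_fpkm"); a single exon ("monoexonic"); coding potential according
#' to either external predictor ("coding_potential"); longest ORF >
#' `max_orf` nt ("long_orf"); or a class code outside `keep_codes`
#' ("class_code"). The removal log records the first failing rule per
#' dropped transcript; the cascade is conjunctive, so survivors do not
#' depend on rule order.
#'
#' @param records data.frame of rows built by [transcript_record()].
#' @param min_exonic,max_orf,keep_codes rule parameters.
#' @return list with `kept` and `log` (columns `id`, `first_fail`; one row
#'   per dropped transcript).
#' @export
filter_lncrna_transcripts <- function(records, min_exonic = 200,
                                      max_orf = 300,
                                      keep_codes = c("x", "i", "j", "u", "o")) {
  stopifnot(nrow(records) > 0)
  orf <- vapply(seq_len(nrow(records)), function(i) {
    if (is.na(records$sequence[i])) 0L
    else longest_orf_length(records$sequence[i])
  }, integer(1))
  rules <- cbind(
    short_exonic = records$exonic_length < min_exonic,
    zero_fpkm = records$max_fpkm == 0,
    monoexonic = records$n_exons == 1,
    coding_potential = records$coding_flag_a | records$coding_flag_b,
    long_orf = orf > max_orf,
    class_code = !(records$class_code %in% keep_codes))
  first_fail <- apply(rules, 1, function(r) {
    f <- which(r)
    if (length(f)) colnames(rules)[min(f)] else NA_character_
  })
  dropped <- !is.na(first_fail)
  list(kept = records[!dropped, , drop = FALSE],
       log = data.frame(id = records$id[dropped],
                        first_fail = first_fail[dropped],
                        stringsAsFactors = FALSE))
}

#' Genes expressed above an FPKM threshold in at least one sample
#'
#' @param gene_fpkm numeric matrix (genes x samples) with gene row names.
#' @param threshold expression cutoff; inclusion requires the row maximum
#'   to be strictly greater than this value.
#' @return character vector of expressed gene ids.
#' @export
expressed_gene_set <- function(gene_fpkm, threshold = 1) {
  stopifnot(is.matrix(gene_fpkm), nrow(gene_fpkm) > 0)
  rownames(gene_fpkm)[apply(gene_fpkm, 1, max) > threshold]
}
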