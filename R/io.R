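#' Read a BED (3 or 6 column) file as a 0-based interval table
#'
#' Comment lines starting with `#` and browser/track lines are tolerated.
#'
#' @param path file path.
#' @return interval data.frame with `chrom`, `start`, `end`, `strand` and,
#'   when present in the file, `name` and `score`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- from_granges0(gr)
  mc <- S4Vectors::mcols(gr)
  if ("name" %in% names(mc)) df$name <- as.character(mc$name)
  if ("score" %in% names(mc) && !all(is.na(mc$score))) df$score <- mc$score
  df
}

#' Write an interval table as BED
#'
#' @param x interval data.frame; `name`/`score` columns are written when
#'   present (6-column BED), otherwise 3-column BED.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  validate_gintervals(x)
  gr <- as_granges0(x)
  if ("name" %in% names(x)) S4Vectors::mcols(gr)$name <- x$name
  if ("score" %in% names(x)) S4Vectors::mcols(gr)$score <- x$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene/transcript/exon features from a GTF file
#'
#' Only `gene`, `transcript` and `exon` features are retained; coordinates
#' are converted to the package's 0-based half-open convention on read.
#'
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `feature`,
#'   `gene_id`, `transcript_id` and, when annotated, `gene_type` and
#'   `class_code`.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "GTF")
  gr <- gr[as.character(gr$type) %in% c("gene", "transcript", "exon")]
  df <- from_granges0(gr)
  df$feature <- as.character(gr$type)
  for (col in c("gene_id", "transcript_id", "gene_type", "class_code")) {
    if (col %in% names(S4Vectors::mcols(gr)))
      df[[col]] <- as.character(S4Vectors::mcols(gr)[[col]])
  }
  df
}

#' Write gene/transcript/exon features as GTF
#'
#' @param x data.frame as returned by [read_gtf()]; `feature` and `gene_id`
#'   are required, `transcript_id` and `class_code` optional.
#' @param path output path.
#' @param source source field for column 2.
#' @export
write_gtf <- function(x, path, source = "ernapipe") {
  validate_gintervals(x)
  stopifnot(all(c("feature", "gene_id") %in% names(x)))
  attrs <- sprintf("gene_id \"%s\";", x$gene_id)
  if ("transcript_id" %in% names(x))
    attrs <- paste(attrs, sprintf("transcript_id \"%s\";", x$transcript_id))
  if ("class_code" %in% names(x))
    attrs <- paste(attrs, sprintf("class_code \"%s\";", x$class_code))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   x$chrom, source, x$feature,
                   as.integer(x$start) + 1L, as.integer(x$end),
                   x$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path file path.
#' @param rna if `TRUE` (default), `T` is mapped to `U` on read so the
#'   sequences can be fed to the RNA-structure routines directly.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path, rna = TRUE) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  if (rna) seqs <- chartr("T", "U", seqs)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write a named character vector of sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read / write tab-separated report tables
#'
#' Thin wrappers around [data.table::fread()] / [data.table::fwrite()];
#' readers tolerate `#` comment lines at the top of the file.
#'
#' @param path file path.
#' @export
read_tsv_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  as.data.frame(data.table::fread(text = paste(lines, collapse = "\n"),
                                  sep = "\t", header = TRUE))
}

#' @rdname read_tsv_file
#' @param x data.frame to write.
#' @export
write_tsv_file <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}
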