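#' Read sequences from FASTA or FASTQ
#'
#' Thin wrappers over [Biostrings::readBStringSet()] that return plain
#' character data canonicalized to the internal RNA alphabet.
#'
#' @param path file path (plain text or gzip).
#' @return `read_fasta`: named character vector of sequences.
#'   `read_fastq`: data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  setNames(rna_canonicalize(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
  q <- S4Vectors::mcols(x)$qualities
  data.frame(id = names(x),
             seq = rna_canonicalize(as.character(x)),
             qual = if (is.null(q)) NA_character_ else as.character(q))
}

#' Write sequences to FASTA / reads to FASTQ
#'
#' FASTA output uses the RNA alphabet (U); FASTQ output uses the DNA alphabet
#' (T), the convention of sequencer-derived files.
#'
#' @param seqs named character vector (FASTA) — unnamed input is given
#'   `seq_1..n` identifiers.
#' @param reads data.frame with `id`, `seq` and optionally `qual` (FASTQ);
#'   missing qualities are written as maximum-confidence placeholders.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  x <- Biostrings::RNAStringSet(rna_canonicalize(unname(seqs)))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  seq_dna <- chartr("Uu", "Tt", reads$seq)
  qual <- reads$qual
  if (is.null(qual) || all(is.na(qual))) qual <- strrep("I", nchar(seq_dna))
  x <- Biostrings::DNAStringSet(seq_dna)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Read / write BED intervals as data.frames
#'
#' BED records are 0-based half-open. Only the first six columns are handled;
#' coordinates may live on genome chromosomes or on per-region coordinate
#' systems (one "chromosome" per transcript region), as the binding-index
#' stage expects.
#'
#' @param path file path.
#' @param x data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @return `read_bed`: data.frame with the available BED columns.
#' @export
read_bed <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#", quote = "")
  names(x) <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(x))]
  x
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  write.table(x[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write two-column expression tables
#'
#' Tab-separated `region_id`, `expression` pairs, as produced by coverage
#' summarization or by [generate_regulome()].
#'
#' @param path file path.
#' @param x data.frame with columns `region_id`, `expression`.
#' @export
read_expression <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("region_id", "expression") %in% names(x)))
  x
}

#' @rdname read_expression
#' @export
write_expression <- function(x, path) {
  stopifnot(all(c("region_id", "expression") %in% names(x)))
  write.table(x[, c("region_id", "expression")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
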