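# File I/O. Sequences are handled internally on the RNA alphabet {A,C,G,U};
# FASTA/FASTQ files use the sequencer convention (T). Readers accept both.

#' Read a FASTA file into a named character vector of RNA sequences
#'
#' @param path path to an (uncompressed) FASTA file; T and U are both
#'   accepted and normalized to U internally.
#' @return named character vector of sequences over \{A,C,G,U,N\}.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as_rna(as.character(x)), names(x))
}

#' Write RNA sequences to FASTA (emitted on the DNA alphabet, T for U)
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  x <- Biostrings::DNAStringSet(as_dna(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path path to an uncompressed FASTQ file.
#' @return data.frame with columns `id`, `seq` (RNA alphabet) and `qual`
#'   (Phred+33 character strings).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = names(x),
    seq = as_rna(as.character(x)),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE
  )
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads data.frame with columns `id`, `seq`, `qual` as returned by
#'   [read_fastq()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)),
            all(nchar(reads$seq) == nchar(reads$qual)))
  x <- Biostrings::DNAStringSet(as_dna(reads$seq))
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' @noRd
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' @noRd
phred_mean <- function(qual) {
  vapply(qual, function(q) {
    if (!nzchar(q)) return(NA_real_)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}
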