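# Read cleaning: adapter trimming, quality / complexity / length gates,
# and collapsing accepted inserts to unique sequences with per-sample counts.

#' Cleaning parameters for raw small-RNA reads
#'
#' @param adapter 3' adapter sequence (required, non-empty).
#' @param min_len,max_len insert length window; only inserts of 18--26 nt
#'   (defaults) survive.
#' @param max_ambiguous maximum number of N bases tolerated in an insert.
#' @param entropy_min minimum Shannon entropy (bits) of the mononucleotide
#'   composition; the low-complexity gate. Homopolymers have entropy 0.
#' @param qual_min minimum mean Phred quality of the insert.
#' @param max_adapter_mismatch mismatch budget for the adapter-prefix search.
#' @return a `clean_params` list.
#' @export
clean_params <- function(adapter, min_len = 18L, max_len = 26L,
                         max_ambiguous = 0L, entropy_min = 1.0,
                         qual_min = 20, max_adapter_mismatch = 1L) {
  stopifnot(is.character(adapter), length(adapter) == 1L, nzchar(adapter),
            min_len <= max_len, entropy_min >= 0, max_ambiguous >= 0)
  structure(list(adapter = as_rna(adapter), min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 max_ambiguous = as.integer(max_ambiguous),
                 entropy_min = entropy_min, qual_min = qual_min,
                 max_adapter_mismatch = as.integer(max_adapter_mismatch)),
            class = "clean_params")
}

#' Locate the 3' adapter and return the upstream insert
#'
#' Scans for the leftmost position where a prefix of the adapter (at least
#' 6 nt of overlap, at most `max_adapter_mismatch` mismatches) starts; the
#' sequence upstream of that position is the insert. Reads that begin with
#' the adapter are adapter dimers and are rejected.
#'
#' @param read read sequence.
#' @param adapter adapter sequence.
#' @param max_adapter_mismatch mismatch budget within the compared prefix.
#' @return list with `insert` (character or `NA`) and `reason`
#'   (`NA`, `"adapter_dimer"` or `"no_adapter"`).
#' @export
trim_adapter <- function(read, adapter, max_adapter_mismatch = 1L) {
  stopifnot(nzchar(adapter))
  pos <- .adapter_scan(as_rna(read), as_rna(adapter),
                       as.integer(max_adapter_mismatch), 6L)
  if (pos < 0L) return(list(insert = NA_character_, reason = "no_adapter"))
  if (pos == 0L) return(list(insert = NA_character_, reason = "adapter_dimer"))
  list(insert = substr(as_rna(read), 1L, pos), reason = NA_character_)
}

#' Apply the length / quality / ambiguity / complexity gates to an insert
#'
#' @param insert insert sequence from [trim_adapter()].
#' @param qual Phred+33 quality string for the insert (same length), or
#'   `NULL` to skip the quality gate.
#' @param params a [clean_params()] object.
#' @return `NA_character_` when accepted, otherwise the rejection reason:
#'   `"length"`, `"quality"`, `"ambiguous"` or `"low_complexity"`.
#' @export
filter_read <- function(insert, qual = NULL, params) {
  n <- nchar(insert)
  if (n < params$min_len || n > params$max_len) return("length")
  if (!is.null(qual) && phred_mean(qual) < params$qual_min) return("quality")
  if (lengths(regmatches(insert, gregexpr("N", insert, fixed = TRUE))) >
      params$max_ambiguous) return("ambiguous")
  if (seq_entropy(insert) < params$entropy_min) return("low_complexity")
  NA_character_
}

#' Shannon entropy of the mononucleotide composition, in bits
#'
#' @param x sequence string.
#' @return entropy in bits per symbol; 0 for homopolymers.
#' @export
seq_entropy <- function(x) {
  chars <- strsplit(x, "")[[1]]
  p <- table(chars) / length(chars)
  -sum(p * log2(p))
}

#' Clean one sample's reads
#'
#' Runs [trim_adapter()] and [filter_read()] over a FASTQ data.frame and
#' tallies every read into exactly one bin (accepted or one rejection
#' reason), so input = accepted + sum(rejected).
#'
#' @param reads data.frame from [read_fastq()].
#' @param params a [clean_params()] object.
#' @return list with `inserts` (character vector of accepted insert
#'   sequences) and `stats` (named integer vector: input, accepted, and one
#'   entry per rejection reason).
#' @export
clean_reads <- function(reads, params) {
  stopifnot(inherits(params, "clean_params"))
  n <- nrow(reads)
  reasons <- character(n)
  inserts <- character(n)
  if (n) {
    pos <- .adapter_scan_many(as_rna(reads$seq), params$adapter,
                              params$max_adapter_mismatch, 6L)
    for (i in seq_len(n)) {
      if (pos[i] < 0L) { reasons[i] <- "no_adapter"; next }
      if (pos[i] == 0L) { reasons[i] <- "adapter_dimer"; next }
      ins <- substr(as_rna(reads$seq[i]), 1L, pos[i])
      q <- substr(reads$qual[i], 1L, pos[i])
      r <- filter_read(ins, q, params)
      if (is.na(r)) {
        inserts[i] <- ins
      } else {
        reasons[i] <- r
      }
    }
  }
  keep <- reasons == ""
  all_reasons <- c("no_adapter", "adapter_dimer", "length", "quality",
                   "ambiguous", "low_complexity")
  stats <- c(input = n, accepted = sum(keep),
             vapply(all_reasons, function(r) sum(reasons == r), integer(1)))
  list(inserts = inserts[keep], stats = stats)
}

#' Collapse accepted inserts into a unique-sequence count table
#'
#' Exact-string grouping of inserts across samples. Rows are ordered by
#' total count descending, ties broken lexicographically by sequence.
#'
#' @param inserts_by_sample named list: one character vector of accepted
#'   insert sequences per sample.
#' @return a `unique_seq_table`: data.frame with column `sequence` followed
#'   by one integer count column per sample.
#' @export
collapse_unique <- function(inserts_by_sample) {
  stopifnot(is.list(inserts_by_sample), !is.null(names(inserts_by_sample)),
            !anyDuplicated(names(inserts_by_sample)))
  samples <- names(inserts_by_sample)
  all_seq <- sort(unique(unlist(inserts_by_sample, use.names = FALSE)))
  counts <- vapply(samples, function(s) {
    tab <- table(factor(inserts_by_sample[[s]], levels = all_seq))
    as.integer(tab)
  }, integer(length(all_seq)))
  if (length(all_seq) == 0L) {
    df <- data.frame(sequence = character(0))
    for (s in samples) df[[s]] <- integer(0)
    class(df) <- c("unique_seq_table", "data.frame")
    return(df)
  }
  counts <- matrix(counts, nrow = length(all_seq),
                   dimnames = list(NULL, samples))
  total <- rowSums(counts)
  ord <- order(-total, all_seq)
  df <- data.frame(sequence = all_seq[ord], stringsAsFactors = FALSE)
  for (s in samples) df[[s]] <- counts[ord, s]
  rownames(df) <- NULL
  class(df) <- c("unique_seq_table", "data.frame")
  df
}

#' Preprocess FASTQ files into a unique-sequence table
#'
#' @param fastq_paths named character vector of FASTQ paths (names are
#'   sample ids).
#' @param params a [clean_params()] object.
#' @return list with `table` (a `unique_seq_table`) and `stats` (matrix of
#'   per-sample read tallies).
#' @export
preprocess_fastq <- function(fastq_paths, params) {
  stopifnot(!is.null(names(fastq_paths)))
  cleaned <- lapply(fastq_paths, function(p) clean_reads(read_fastq(p), params))
  stats <- do.call(rbind, lapply(cleaned, `[[`, "stats"))
  rownames(stats) <- names(fastq_paths)
  list(table = collapse_unique(lapply(cleaned, `[[`, "inserts")),
       stats = stats)
}
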