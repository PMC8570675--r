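# Count-matrix assembly and the median-of-ratios library-size
# normalization: S_j = median_i ( c_ij / (prod_k c_ik)^(1/m) ), where the
# pseudo-reference for row i is the geometric mean of its counts across all
# m samples, and the median runs over rows with all counts positive.

#' Build a miRNA x sample count matrix from annotation results
#'
#' One row per mature miRNA (`known_mature` assignments, keyed by mature
#' id) and, optionally, per accepted novel candidate (keyed by
#' `precursor_id` with a `novel-` prefix). Each cell sums the counts of
#' the unique sequences assigned to that row; totals are conserved.
#'
#' @param annotation an `annotation_result` from [annotate_table()].
#' @param accepted_novel character vector of sequences (rows of
#'   `annotation`) whose candidate windows passed the structural criteria;
#'   others are dropped.
#' @return integer matrix with row ids as rownames and sample ids as
#'   colnames.
#' @export
build_count_matrix <- function(annotation, accepted_novel = character(0)) {
  sample_cols <- setdiff(names(annotation),
                         c("sequence", "class", "precursor_id", "start",
                           "end", "mismatches", "mature_id",
                           "window_start", "window_end"))
  known <- annotation[annotation$class == "known_mature", , drop = FALSE]
  nov <- annotation[annotation$class == "novel_arm_candidate" &
                      annotation$sequence %in% accepted_novel, , drop = FALSE]
  ids <- c(known$mature_id, if (nrow(nov)) paste0("novel-", nov$precursor_id))
  if (!length(ids)) {
    return(matrix(integer(0), nrow = 0, ncol = length(sample_cols),
                  dimnames = list(NULL, sample_cols)))
  }
  dat <- rbind(known[, sample_cols, drop = FALSE],
               nov[, sample_cols, drop = FALSE])
  agg <- rowsum(as.matrix(dat), group = ids)
  storage.mode(agg) <- "integer"
  agg[order(rownames(agg)), , drop = FALSE]
}

#' Library-size factors by the median-of-ratios rule
#'
#' For each row i the pseudo-reference count is the geometric mean of
#' `c_ij` across samples (computed in log space); the factor of sample j is
#' the median over reference rows of `c_ij` divided by that
#' pseudo-reference. Reference rows are the rows with all counts positive
#' (the geometric mean is undefined at zero); with `pseudocount = TRUE`
#' every count gets +0.5 instead and all rows are used.
#'
#' @param mat count matrix (rows = miRNAs, columns = samples).
#' @param pseudocount add 0.5 to every count instead of dropping rows with
#'   zeros.
#' @return a `library_size_factors` object: numeric vector `S_j` (one per
#'   sample, all positive) with attribute `reference_rows`.
#' @export
library_size_factors <- function(mat, pseudocount = FALSE) {
  stopifnot(is.matrix(mat), ncol(mat) >= 1)
  work <- if (pseudocount) mat + 0.5 else mat
  ref <- which(apply(work > 0, 1, all))
  if (!length(ref)) {
    stop("no row with all counts positive; filter rows or use pseudocount = TRUE")
  }
  logw <- log(work[ref, , drop = FALSE])
  pseudo_ref <- rowMeans(logw)                 # log geometric mean
  s <- apply(exp(logw - pseudo_ref), 2, median)
  structure(setNames(s, colnames(mat)),
            reference_rows = rownames(mat)[ref],
            class = "library_size_factors")
}

#' Normalize a count matrix by library-size factors
#'
#' @param mat count matrix.
#' @param factors factors from [library_size_factors()] computed on a
#'   matrix with the same samples.
#' @return numeric matrix of `c_ij / S_j`; zeros stay zero.
#' @export
normalize_counts <- function(mat, factors) {
  stopifnot(inherits(factors, "library_size_factors"))
  if (!identical(colnames(mat), names(factors))) {
    stop("sample ids of matrix and factors do not match")
  }
  sweep(mat, 2, unclass(factors), "/")
}
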