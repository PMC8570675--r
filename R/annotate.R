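# Annotation of unique sequences: contaminant removal, ungapped
# mismatch/end-shift tolerant mapping onto precursor hairpins, and the
# known / novel-arm / unmapped classification.
#
# Tolerances follow the mapping rules of the screening workflow: length
# variation at both ends (default up to 2 nt per end) and at most one
# internal mismatch; alignments are strictly ungapped and sense-strand.
# Coordinates are 1-based inclusive throughout (the R/Bioconductor
# convention).

#' Build a precursor reference
#'
#' @param precursors data.frame with columns `id` and `sequence`
#'   (precursor hairpins, RNA or DNA alphabet).
#' @param matures data.frame with columns `precursor_id`, `mature_id`,
#'   `arm` (`"5p"` or `"3p"`) and `start`, `end` (1-based inclusive
#'   coordinates within the precursor).
#' @return a `precursor_reference` object.
#' @export
precursor_reference <- function(precursors, matures) {
  stopifnot(all(c("id", "sequence") %in% names(precursors)),
            all(c("precursor_id", "mature_id", "arm", "start", "end") %in%
                  names(matures)),
            !anyDuplicated(precursors$id),
            !anyDuplicated(matures$mature_id),
            all(matures$precursor_id %in% precursors$id),
            all(matures$arm %in% c("5p", "3p")))
  precursors$sequence <- as_rna(precursors$sequence)
  len <- setNames(nchar(precursors$sequence), precursors$id)
  stopifnot(all(matures$start >= 1),
            all(matures$end <= len[matures$precursor_id]),
            all(matures$start <= matures$end))
  structure(list(precursors = precursors, matures = matures),
            class = "precursor_reference")
}

#' Partition a unique-sequence table into contaminant and retained rows
#'
#' A sequence is a contaminant iff it occurs as an exact substring of any
#' contaminant record (sense strand only; small-RNA libraries are
#' stranded). Counts are conserved across the partition.
#'
#' @param table a `unique_seq_table` from [collapse_unique()].
#' @param contaminants named character vector of contaminant ncRNA
#'   sequences (rRNA/tRNA/snRNA/snoRNA stand-ins); empty vector removes
#'   nothing.
#' @return list with `retained` and `contaminant` tables.
#' @export
remove_contaminants <- function(table, contaminants) {
  if (!length(contaminants) || !nrow(table)) {
    return(list(retained = table, contaminant = table[integer(0), , drop = FALSE]))
  }
  cont <- as_rna(contaminants)
  is_cont <- vapply(table$sequence, function(s) {
    any(vapply(cont, function(cc) grepl(s, cc, fixed = TRUE), logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  list(retained = table[!is_cont, , drop = FALSE],
       contaminant = table[is_cont, , drop = FALSE])
}

#' Map one sequence onto the precursor reference
#'
#' Enumerates every ungapped placement of the sequence on every precursor
#' and keeps placements with at most `max_mismatch` internal mismatches.
#' A placement is mature-consistent when both of its ends lie within
#' `max_end_shift` nt of an annotated mature interval's ends. Hits are
#' ranked by (mismatches, total end shift); the earliest-listed precursor
#' wins remaining ties.
#'
#' @param sequence an 18--26 nt unique sequence.
#' @param reference a [precursor_reference()].
#' @param max_mismatch maximum internal mismatches (default 1).
#' @param max_end_shift maximum shift per end against a mature annotation
#'   (default 2 nt).
#' @return data.frame of hits: `precursor_id`, `start`, `end`,
#'   `mismatches`, `mature_id` (`NA` when not mature-consistent),
#'   `shift5`, `shift3`, `end_shift`, ordered by rank; zero rows when the
#'   sequence has no placement.
#' @export
map_to_precursors <- function(sequence, reference, max_mismatch = 1L,
                              max_end_shift = 2L) {
  stopifnot(inherits(reference, "precursor_reference"))
  s <- as_rna(sequence)
  ns <- nchar(s)
  hits <- list()
  for (pi in seq_len(nrow(reference$precursors))) {
    pid <- reference$precursors$id[pi]
    pseq <- reference$precursors$sequence[pi]
    if (ns > nchar(pseq)) next
    mm <- .mismatch_scan(s, pseq)
    ok <- which(mm <= max_mismatch)
    if (!length(ok)) next
    mat <- reference$matures[reference$matures$precursor_id == pid, , drop = FALSE]
    for (o in ok) {
      h_start <- o                 # R index over 0-based offsets == 1-based start
      h_end <- o + ns - 1L
      best_m <- NA_character_; s5 <- NA_integer_; s3 <- NA_integer_
      if (nrow(mat)) {
        d5 <- abs(h_start - mat$start)
        d3 <- abs(h_end - mat$end)
        cons <- which(d5 <= max_end_shift & d3 <= max_end_shift)
        if (length(cons)) {
          b <- cons[which.min(d5[cons] + d3[cons])]
          best_m <- mat$mature_id[b]; s5 <- d5[b]; s3 <- d3[b]
        }
      }
      hits[[length(hits) + 1L]] <- data.frame(
        precursor_id = pid, start = h_start, end = h_end,
        mismatches = mm[o], mature_id = best_m,
        shift5 = s5, shift3 = s3,
        end_shift = ifelse(is.na(s5), NA_integer_, s5 + s3),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(precursor_id = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      mature_id = character(0), shift5 = integer(0),
                      shift3 = integer(0), end_shift = integer(0)))
  }
  df <- do.call(rbind, hits)
  prec_rank <- match(df$precursor_id, reference$precursors$id)
  shift_rank <- ifelse(is.na(df$end_shift), max_end_shift * 2L + 1L,
                       df$end_shift)
  df <- df[order(df$mismatches, shift_rank, prec_rank, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# internal: arm side of an interval on a precursor, from the folded
# terminal loop of the dominant hairpin. Returns "5p", "3p" or NA (spans
# the loop).
#' @noRd
interval_arm <- function(pseq, start, end) {
  st <- fold(pseq)
  hps <- find_hairpins(st$pairs)
  if (!length(hps)) return(NA_character_)
  bp <- vapply(hps, function(h) h$stem_bp, integer(1))
  hp <- hps[[which.max(bp)]]
  if (end < hp$loop_start) return("5p")
  if (start > hp$loop_end) return("3p")
  NA_character_
}

#' Classify one unique sequence from its mapping hits
#'
#' Mature-consistent best hit: `known_mature`. A hit on the arm opposite
#' the sole annotated mature of a precursor: `novel_arm_candidate`, with an
#' 80 nt flank window centred on the placement (clipped to precursor
#' bounds) recorded for structural assessment. Anything else: `unmapped`.
#'
#' @param sequence the unique sequence.
#' @param hits data.frame from [map_to_precursors()].
#' @param reference a [precursor_reference()].
#' @param flank total width (nt) of the candidate window (default 80).
#' @return one-row data.frame: `sequence`, `class`, `precursor_id`,
#'   `start`, `end`, `mismatches`, `mature_id`, `window_start`,
#'   `window_end`.
#' @export
classify_hit <- function(sequence, hits, reference, flank = 80L) {
  row <- data.frame(sequence = as_rna(sequence), class = "unmapped",
                    precursor_id = NA_character_, start = NA_integer_,
                    end = NA_integer_, mismatches = NA_integer_,
                    mature_id = NA_character_, window_start = NA_integer_,
                    window_end = NA_integer_, stringsAsFactors = FALSE)
  if (!nrow(hits)) return(row)
  mature_hits <- hits[!is.na(hits$mature_id), , drop = FALSE]
  if (nrow(mature_hits)) {
    h <- mature_hits[1L, ]
    row$class <- "known_mature"
    row$precursor_id <- h$precursor_id; row$start <- h$start
    row$end <- h$end; row$mismatches <- h$mismatches
    row$mature_id <- h$mature_id
    return(row)
  }
  # novel-arm scan: best-ranked hit whose precursor has a single annotated
  # mature on the opposite arm of the placement
  for (k in seq_len(nrow(hits))) {
    h <- hits[k, ]
    mat <- reference$matures[reference$matures$precursor_id == h$precursor_id, ,
                             drop = FALSE]
    if (nrow(mat) != 1L) next
    pseq <- reference$precursors$sequence[
      reference$precursors$id == h$precursor_id]
    hit_arm <- interval_arm(pseq, h$start, h$end)
    if (is.na(hit_arm) || hit_arm == mat$arm) next
    centre <- (h$start + h$end) %/% 2L
    half <- flank %/% 2L
    ws <- max(1L, centre - half + 1L)
    we <- min(nchar(pseq), ws + flank - 1L)
    ws <- max(1L, we - flank + 1L)   # re-clip at the 3' boundary
    row$class <- "novel_arm_candidate"
    row$precursor_id <- h$precursor_id; row$start <- h$start
    row$end <- h$end; row$mismatches <- h$mismatches
    row$window_start <- ws; row$window_end <- we
    return(row)
  }
  row
}

#' Annotate a unique-sequence table against a precursor reference
#'
#' Runs contaminant removal, mapping and classification over every row.
#' Classes are mutually exclusive and exhaustive:
#' `known_mature`, `novel_arm_candidate`, `contaminant`, `unmapped`.
#'
#' @param table a `unique_seq_table`.
#' @param reference a [precursor_reference()].
#' @param contaminants named character vector of contaminant sequences
#'   (may be empty).
#' @param max_mismatch,max_end_shift mapping tolerances; see
#'   [map_to_precursors()].
#' @param flank candidate window width; see [classify_hit()].
#' @return an `annotation_result`: data.frame with one row per unique
#'   sequence (classification columns followed by the per-sample counts).
#' @export
annotate_table <- function(table, reference, contaminants = character(0),
                           max_mismatch = 1L, max_end_shift = 2L,
                           flank = 80L) {
  part <- remove_contaminants(table, contaminants)
  sample_cols <- setdiff(names(table), "sequence")
  rows <- lapply(seq_len(nrow(part$retained)), function(i) {
    s <- part$retained$sequence[i]
    hits <- map_to_precursors(s, reference, max_mismatch, max_end_shift)
    classify_hit(s, hits, reference, flank)
  })
  ann <- if (length(rows)) do.call(rbind, rows) else classify_hit("ACGUACGUACGUACGUAC",
    data.frame(), reference)[0, ]
  if (nrow(part$contaminant)) {
    cont <- data.frame(sequence = part$contaminant$sequence,
                       class = "contaminant", precursor_id = NA_character_,
                       start = NA_integer_, end = NA_integer_,
                       mismatches = NA_integer_, mature_id = NA_character_,
                       window_start = NA_integer_, window_end = NA_integer_,
                       stringsAsFactors = FALSE)
    ann <- rbind(ann, cont)
  }
  counts <- rbind(part$retained, part$contaminant)
  ann <- cbind(ann, counts[match(ann$sequence, counts$sequence), sample_cols,
                           drop = FALSE])
  rownames(ann) <- NULL
  class(ann) <- c("annotation_result", "data.frame")
  ann
}
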