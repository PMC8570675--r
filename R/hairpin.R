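# Secondary-structure prediction and the eleven structural criteria used to
# screen novel miRNA hairpin candidates.
#
# The folder is a self-contained energy-minimizing dynamic program over
# non-crossing base pairs with per-pair energies (GC -3.0, AU -2.0, GU -1.0
# kcal/mol) and a minimum hairpin loop of 3 nt. It is not a full
# nearest-neighbor thermodynamic model; the free-energy criterion therefore
# applies on this model's scale and is configurable. A dot-bracket string
# plus energy produced by an external folder can be injected through
# `secondary_structure()` without touching downstream code.

#' Fold an RNA sequence into its minimum-energy non-crossing structure
#'
#' Minimizes total pairing energy under a simple per-pair model
#' (GC = -3.0, AU = -2.0, GU = -1.0 kcal/mol; hairpin loops of at least
#' 3 nt; no pseudoknots). Ties are broken deterministically: pairing is
#' preferred over leaving a base unpaired, and the 5'-most partner wins.
#'
#' @param sequence a single RNA/DNA string (10--200 nt) over
#'   \{A,C,G,U,T,N\}; N never pairs.
#' @return a `secondary_structure` object: list with `sequence`,
#'   `dotbracket`, `pairs` (1-based partner index, `NA` when unpaired) and
#'   `energy` (kcal/mol, 0 when no pair exists).
#' @examples
#' fold("GGGGAAAACCCC")$dotbracket  # "((((....))))", energy -12
#' @export
fold <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- as_rna(sequence)
  n <- nchar(seq)
  if (n < 10 || n > 200) {
    stop("fold() expects a sequence of 10 to 200 nt, got ", n)
  }
  res <- .fold_dp(seq)
  pairs <- res$pairs
  pairs[pairs == 0L] <- NA_integer_
  db <- rep(".", n)
  paired <- which(!is.na(pairs))
  db[paired[pairs[paired] > paired]] <- "("
  db[paired[pairs[paired] < paired]] <- ")"
  secondary_structure(seq, paste(db, collapse = ""), res$energy)
}

#' Construct a secondary-structure object from a dot-bracket string
#'
#' Entry point for structures computed elsewhere (e.g. an external folder's
#' plain-text output): downstream feature extraction and criteria
#' evaluation only consume this container.
#'
#' @param sequence RNA/DNA string.
#' @param dotbracket dot-bracket string of the same length; must be
#'   balanced and non-crossing.
#' @param energy free energy in kcal/mol (\eqn{\le 0} if any pair exists).
#' @return a `secondary_structure` object.
#' @export
secondary_structure <- function(sequence, dotbracket, energy) {
  seq <- as_rna(sequence)
  n <- nchar(seq)
  stopifnot(nchar(dotbracket) == n)
  chars <- strsplit(dotbracket, "")[[1]]
  if (!all(chars %in% c("(", ")", "."))) stop("invalid dot-bracket characters")
  pairs <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j
      pairs[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  if (any(!is.na(pairs)) && energy > 0) {
    stop("energy must be <= 0 when any base pair exists")
  }
  structure(
    list(sequence = seq, dotbracket = dotbracket, pairs = pairs,
         energy = energy),
    class = "secondary_structure"
  )
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, " (", format(x$energy), " kcal/mol)\n",
      sep = "")
  invisible(x)
}

# internal: enumerate hairpins (terminal loop + nested stem chain) ------------
# A hairpin is an innermost pair (a, b) with no paired base inside, extended
# outward through consecutively nested pairs separated only by unpaired nt
# (bulges / interior loops). Multiloop branching ends the chain.
#' @noRd
find_hairpins <- function(pairs) {
  n <- length(pairs)
  hairpins <- list()
  for (a in seq_len(n)) {
    b <- pairs[a]
    if (is.na(b) || b <= a) next
    inside <- if (b - a > 1) (a + 1):(b - 1) else integer(0)
    if (any(!is.na(pairs[inside]))) next  # not innermost
    chain_i <- a
    chain_j <- b
    i <- a; j <- b
    repeat {
      # nearest paired position 5' of i
      left <- if (i > 1) rev(which(!is.na(pairs[seq_len(i - 1)]))) else integer(0)
      if (!length(left)) break
      i2 <- left[1]
      j2 <- pairs[i2]
      if (is.na(j2) || j2 <= j) break           # not enclosing: chain ends
      gap3 <- if (j2 - j > 1) (j + 1):(j2 - 1) else integer(0)
      if (any(!is.na(pairs[gap3]))) break       # branch on the 3' side
      chain_i <- c(chain_i, i2)
      chain_j <- c(chain_j, j2)
      i <- i2; j <- j2
    }
    hairpins[[length(hairpins) + 1L]] <- list(
      loop_start = a + 1L, loop_end = b - 1L,
      loop_len = b - a - 1L,
      stem_i = chain_i, stem_j = chain_j,      # innermost -> outermost
      span = c(i, j),
      stem_bp = length(chain_i)
    )
  }
  hairpins
}

# internal: unpaired runs between consecutive stem pairs, with strand sides.
# Returns data.frame(start, end, len, side, opposite_len).
#' @noRd
stem_bulges <- function(hp) {
  k <- hp$stem_bp
  if (k < 2) {
    return(data.frame(start = integer(0), end = integer(0), len = integer(0),
                      side = character(0), opposite_len = integer(0)))
  }
  out <- list()
  for (t in seq_len(k - 1)) {
    i_in <- hp$stem_i[t];  j_in <- hp$stem_j[t]      # inner pair
    i_out <- hp$stem_i[t + 1]; j_out <- hp$stem_j[t + 1]
    len5 <- i_in - i_out - 1L
    len3 <- j_out - j_in - 1L
    if (len5 > 0) {
      out[[length(out) + 1L]] <- data.frame(
        start = i_out + 1L, end = i_in - 1L, len = len5, side = "5p",
        opposite_len = len3)
    }
    if (len3 > 0) {
      out[[length(out) + 1L]] <- data.frame(
        start = j_in + 1L, end = j_out - 1L, len = len3, side = "3p",
        opposite_len = len5)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0), len = integer(0),
                      side = character(0), opposite_len = integer(0)))
  }
  do.call(rbind, out)
}

#' Extract hairpin features for criteria evaluation
#'
#' Identifies the dominant hairpin of the folded structure (the hairpin
#' whose stem span contains the mature placement; if none does, the hairpin
#' with the most stem base pairs) and measures the quantities consumed by
#' the structural criteria: stem base pairs, largest stem bulge, hairpin
#' and loop lengths, and the mature-region pairing statistics.
#'
#' A bulge is a maximal run of unpaired nucleotides between two consecutive
#' stem pairs; it is "biased" when the opposite strand of the stem has no
#' unpaired nucleotide at that position (all the slack sits on one strand).
#' Mature-region "errors" are unpaired nucleotides within the mature
#' interval.
#'
#' @param struct a `secondary_structure`.
#' @param mature integer vector `c(start, end)`, 1-based inclusive interval
#'   of the candidate mature sequence within `struct$sequence`; `NULL` when
#'   only stem-level features are needed.
#' @return a `hairpin_features` list with fields `stem_bp`,
#'   `stem_bulge_max`, `hairpin_len`, `loop_len`, `mature_bp`,
#'   `mature_errors`, `mature_bulge_max`, `biased_mature_bulges`,
#'   `biased_errors_max`, `pct_mature_in_stem`.
#' @export
extract_features <- function(struct, mature = NULL) {
  stopifnot(inherits(struct, "secondary_structure"))
  n <- nchar(struct$sequence)
  if (!is.null(mature)) {
    stopifnot(length(mature) == 2, mature[1] >= 1, mature[2] <= n,
              mature[1] <= mature[2])
  }
  zero <- structure(list(
    stem_bp = 0L, stem_bulge_max = 0L, hairpin_len = 0L, loop_len = 0L,
    mature_bp = 0L, mature_errors = 0L, mature_bulge_max = 0L,
    biased_mature_bulges = 0L, biased_errors_max = 0L,
    pct_mature_in_stem = 0), class = "hairpin_features")
  hps <- find_hairpins(struct$pairs)
  if (!length(hps)) return(zero)

  pick <- NULL
  if (!is.null(mature)) {
    containing <- Filter(function(h) mature[1] >= h$span[1] && mature[2] <= h$span[2], hps)
    if (length(containing)) pick <- containing
  }
  if (is.null(pick)) pick <- hps
  bp <- vapply(pick, function(h) h$stem_bp, integer(1))
  hp <- pick[[order(-bp, vapply(pick, function(h) h$span[1], integer(1)))[1]]]

  bulges <- stem_bulges(hp)
  feats <- zero
  feats$stem_bp <- hp$stem_bp
  feats$stem_bulge_max <- if (nrow(bulges)) max(bulges$len) else 0L
  feats$hairpin_len <- hp$span[2] - hp$span[1] + 1L
  feats$loop_len <- hp$loop_len

  if (!is.null(mature)) {
    mpos <- mature[1]:mature[2]
    paired <- !is.na(struct$pairs[mpos])
    feats$mature_bp <- sum(paired)
    feats$mature_errors <- sum(!paired)
    # stem arm spans: outermost pair .. innermost pair on each strand
    arm5 <- c(hp$span[1], hp$stem_i[1])
    arm3 <- c(hp$stem_j[1], hp$span[2])
    in_stem <- (mpos >= arm5[1] & mpos <= arm5[2]) |
               (mpos >= arm3[1] & mpos <= arm3[2])
    feats$pct_mature_in_stem <- 100 * sum(in_stem) / length(mpos)
    if (nrow(bulges)) {
      hit <- bulges$start <= mature[2] & bulges$end >= mature[1]
      mb <- bulges[hit, , drop = FALSE]
      if (nrow(mb)) {
        feats$mature_bulge_max <- max(mb$len)
        biased <- mb$opposite_len == 0L
        feats$biased_mature_bulges <- sum(biased)
        feats$biased_errors_max <- if (any(biased)) max(mb$len[biased]) else 0L
      }
    }
  }
  feats
}

#' Default thresholds of the eleven hairpin criteria
#'
#' The screening thresholds for accepting a candidate hairpin:
#' \enumerate{
#'   \item nucleotides in one stem bulge \eqn{\le 12}
#'   \item base pairs in the stem \eqn{\ge 16}
#'   \item free energy \eqn{\le -15} kcal/mol
#'   \item hairpin length (both stems + terminal loop) \eqn{\ge 50} nt
#'   \item terminal loop length \eqn{\le 20} nt
#'   \item nucleotides in one mature-region bulge \eqn{\le 8}
#'   \item biased errors in one mature-region bulge \eqn{\le 4}
#'   \item biased bulges in the mature region \eqn{\le 2}
#'   \item errors (unpaired nt) in the mature region \eqn{\le 7}
#'   \item base pairs in the mature region \eqn{\ge 12}
#'   \item percent of the mature sequence inside the stem \eqn{\ge 80}
#' }
#' All comparisons are boundary-inclusive.
#'
#' @param ... named overrides of individual thresholds (`c1` .. `c11`).
#' @return named numeric vector of length 11.
#' @export
criteria_thresholds <- function(...) {
  th <- c(c1 = 12, c2 = 16, c3 = -15, c4 = 50, c5 = 20, c6 = 8, c7 = 4,
          c8 = 2, c9 = 7, c10 = 12, c11 = 80)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(th))
    if (length(bad)) stop("unknown criteria: ", paste(bad, collapse = ", "))
    th[names(dots)] <- unlist(dots)
  }
  th
}

#' Evaluate the eleven structural criteria for a candidate hairpin
#'
#' @param features a `hairpin_features` object from [extract_features()].
#' @param energy free energy of the structure in kcal/mol.
#' @param thresholds thresholds from [criteria_thresholds()].
#' @return a named logical vector `c1` .. `c11` plus `overall`
#'   (`TRUE` iff all eleven criteria hold).
#' @export
evaluate_criteria <- function(features, energy,
                              thresholds = criteria_thresholds()) {
  stopifnot(all(is.finite(unlist(features))), is.finite(energy))
  f <- features
  th <- thresholds
  crit <- c(
    c1  = f$stem_bulge_max       <= th[["c1"]],
    c2  = f$stem_bp              >= th[["c2"]],
    c3  = energy                 <= th[["c3"]],
    c4  = f$hairpin_len          >= th[["c4"]],
    c5  = f$loop_len             <= th[["c5"]],
    c6  = f$mature_bulge_max     <= th[["c6"]],
    c7  = f$biased_errors_max    <= th[["c7"]],
    c8  = f$biased_mature_bulges <= th[["c8"]],
    c9  = f$mature_errors        <= th[["c9"]],
    c10 = f$mature_bp            >= th[["c10"]],
    c11 = f$pct_mature_in_stem   >= th[["c11"]]
  )
  c(crit, overall = all(crit))
}

#' Fold a candidate window and apply the eleven criteria
#'
#' Convenience wrapper: folds the sequence, extracts features relative to
#' the mature placement, and evaluates the criteria.
#'
#' @inheritParams fold
#' @param mature 1-based inclusive `c(start, end)` of the candidate mature
#'   within the window.
#' @param thresholds see [criteria_thresholds()].
#' @return list with `structure`, `features` and `criteria`.
#' @export
assess_candidate <- function(sequence, mature,
                             thresholds = criteria_thresholds()) {
  st <- fold(sequence)
  fe <- extract_features(st, mature)
  list(structure = st, features = fe,
       criteria = evaluate_criteria(fe, st$energy, thresholds))
}

#' Write structures in Vienna-style plain text
#'
#' One record per structure: a `>` header line, the sequence, then the
#' dot-bracket string with the energy in parentheses.
#'
#' @param structures named list of `secondary_structure` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(structures, path) {
  stopifnot(!is.null(names(structures)))
  lines <- unlist(lapply(names(structures), function(nm) {
    s <- structures[[nm]]
    c(paste0(">", nm), s$sequence,
      sprintf("%s (%.2f)", s$dotbracket, s$energy))
  }))
  writeLines(lines, path)
  invisible(path)
}
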